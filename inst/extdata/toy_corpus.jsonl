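{"text":"growth cell tumor cell mutation therapy therapy mutation tumor growth mutation virus vaccine","year":2001,"label":"NCI"}
{"text":"synapse neuron memory neuron neuron imaging synapse mutation cortex","year":2002,"label":"NIMH"}
{"text":"vaccine virus pathogen infection vaccine antibody infection antibody virus immune mutation vaccine","year":2003,"label":"NIAID"}
{"text":"mutation cell cell therapy therapy mutation growth mutation tumor tumor tumor antibody","year":2000,"label":"NCI"}
{"text":"imaging memory brain imaging brain imaging synapse brain brain neuron imaging tumor neuron","year":2001,"label":"NIMH"}
{"text":"virus immune immune antibody antibody pathogen immune immune virus infection virus antibody infection brain","year":2002,"label":"NIAID"}
{"text":"oncogene mutation growth therapy growth mutation mutation growth memory","year":2003,"label":"NCI"}
{"text":"imaging synapse neuron synapse memory synapse neuron infection therapy","year":2000,"label":"NIMH"}
{"text":"virus infection infection antibody antibody vaccine infection vaccine synapse mutation","year":2001,"label":"NIAID"}
{"text":"cell growth growth growth tumor therapy oncogene growth growth brain oncogene","year":2002,"label":"NCI"}
{"text":"neuron imaging neuron memory imaging memory memory neuron memory synapse brain immune","year":2003,"label":"NIMH"}
{"text":"vaccine vaccine pathogen infection vaccine immune immune infection vaccine antibody cortex memory","year":2000,"label":"NIAID"}
{"text":"growth tumor cell therapy cell growth cell oncogene growth cell oncogene therapy oncogene imaging","year":2001,"label":"NCI"}
{"text":"neuron brain brain brain neuron imaging tumor imaging","year":2002,"label":"NIMH"}
{"text":"infection pathogen antibody virus infection infection antibody vaccine pathogen tumor","year":2003,"label":"NIAID"}
{"text":"mutation cell cell oncogene oncogene cell oncogene mutation mutation oncogene imaging","year":2000,"label":"NCI"}
{"text":"memory imaging memory synapse cortex neuron neuron synapse imaging neuron synapse neuron","year":2001,"label":"NIMH"}
{"text":"vaccine infection antibody infection vaccine virus vaccine pathogen virus antibody synapse cortex","year":2002,"label":"NIAID"}
{"text":"cell growth cell therapy tumor mutation tumor oncogene cell vaccine imaging","year":2003,"label":"NCI"}
{"text":"brain synapse neuron cortex memory memory memory neuron virus imaging","year":2000,"label":"NIMH"}
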