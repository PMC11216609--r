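#' Time-sliced bag-of-words corpus
#'
#' A `tm_corpus` bundles a sparse document-by-term count matrix with the
#' per-document metadata (time slice, calendar year, label) that the dynamic
#' topic model needs. Documents are rows; the vocabulary is shared across all
#' time slices. Slices are numbered `1..T` in ascending calendar order and
#' every slice present holds at least one document at construction time.
#'
#' @param counts sparse (or dense) non-negative integer matrix, documents in
#'   rows, one column per vocabulary term.
#' @param docs tibble with one row per document and columns `doc_id`
#'   (character, unique), `slice` (integer in `1..T`), `year` (integer),
#'   `label` (integer in `1..M`).
#' @param vocabulary character vector of unique terms, one per column of
#'   `counts`.
#' @param label_names character vector of the `M` label categories.
#' @param years integer vector of length `T`, the calendar year of each slice,
#'   strictly increasing.
#' @return an object of class `tm_corpus`.
#' @export
new_tm_corpus <- function(counts, docs, vocabulary, label_names, years) {
  if (inherits(counts, "nMatrix") || inherits(counts, "lMatrix"))
    counts <- 1 * counts   # pattern/logical (e.g. a binary MTX) -> numeric
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
  docs <- tibble::as_tibble(docs)
  stopifnot(
    nrow(counts) == nrow(docs),
    ncol(counts) == length(vocabulary),
    !anyDuplicated(vocabulary),
    all(diff(years) > 0),
    all(docs$slice >= 1L), all(docs$slice <= length(years)),
    all(docs$label >= 1L), all(docs$label <= length(label_names))
  )
  if (any(counts@x < 0)) stop("negative counts are not allowed")
  colnames(counts) <- vocabulary
  structure(
    list(counts = counts, docs = docs, vocabulary = vocabulary,
         label_names = label_names, years = years),
    class = "tm_corpus"
  )
}

#' @export
print.tm_corpus <- function(x, ...) {
  cat(sprintf(
    "<tm_corpus> %d documents, %d terms, %d slices (%d-%d), %d labels\n",
    nrow(x$counts), length(x$vocabulary), length(x$years),
    min(x$years), max(x$years), length(x$label_names)
  ))
  n_by_slice <- tabulate(x$docs$slice, nbins = length(x$years))
  cat("  docs per slice: ", paste(n_by_slice, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Number of documents, terms, slices and labels of a corpus
#' @param corpus a [tm_corpus][new_tm_corpus].
#' @return named list with `n_docs`, `n_terms`, `n_slices`, `n_labels`.
#' @export
corpus_dims <- function(corpus) {
  list(n_docs = nrow(corpus$counts), n_terms = length(corpus$vocabulary),
       n_slices = length(corpus$years), n_labels = length(corpus$label_names))
}

# Subset a corpus by document index, keeping slice/vocab structure intact.
subset_corpus <- function(corpus, idx) {
  new_tm_corpus(corpus$counts[idx, , drop = FALSE], corpus$docs[idx, ],
                corpus$vocabulary, corpus$label_names, corpus$years)
}

#' Built-in English stopword list
#'
#' A deliberately small list of function words used as the default stopword
#' filter; pass your own vector to [preprocess_corpus()] for serious work.
#' @return character vector.
#' @export
default_stopwords <- function() {
  c("a", "about", "above", "after", "again", "all", "also", "an", "and",
    "any", "are", "as", "at", "be", "because", "been", "before", "being",
    "between", "both", "but", "by", "can", "could", "did", "do", "does",
    "doing", "during", "each", "for", "from", "further", "had", "has",
    "have", "having", "he", "her", "here", "hers", "him", "his", "how",
    "i", "if", "in", "into", "is", "it", "its", "itself", "just", "more",
    "most", "my", "no", "nor", "not", "now", "of", "off", "on", "once",
    "only", "or", "other", "our", "out", "over", "own", "same", "she",
    "should", "so", "some", "such", "than", "that", "the", "their",
    "them", "then", "there", "these", "they", "this", "those", "through",
    "to", "too", "under", "until", "up", "very", "was", "we", "were",
    "what", "when", "where", "which", "while", "who", "whom", "why",
    "will", "with", "would", "you", "your", "yours")
}

# Lowercase and split raw text into word tokens.
tokenize_text <- function(x) {
  stringr::str_extract_all(stringr::str_to_lower(x), "[a-z][a-z0-9'-]*")
}

#' Build a time-sliced bag-of-words corpus from raw documents
#'
#' Tokenizes (unless already tokenized), optionally lemmatizes, and applies
#' the standard topic-modeling filters: stopword removal, a maximum
#' document-frequency cut (words present in more than `max_df` of all
#' documents are dropped), a minimum corpus-wide count, and removal of
#' documents left with fewer than `min_doc_len` tokens. Surviving calendar
#' years are mapped, in ascending order, to contiguous slice indices; years
#' with no surviving documents produce no slice.
#'
#' Defaults follow common practice for large grant/abstract corpora: words in
#' more than 80% of documents or seen fewer than 10 times corpus-wide are
#' removed, as are documents shorter than 10 tokens after filtering.
#'
#' @param docs data frame with columns `text` (character, or a list column of
#'   token vectors), `year` (integer) and `label` (character or factor).
#' @param stopwords character vector of words to drop; see
#'   [default_stopwords()].
#' @param max_df maximum document frequency as a fraction of all documents,
#'   in (0, 1].
#' @param min_count minimum corpus-wide occurrence count for a word to enter
#'   the vocabulary.
#' @param min_doc_len minimum total token count for a document to survive.
#' @param lemmatizer optional function mapping a character vector of tokens
#'   to a same-length vector of lemmas; default `NULL` leaves tokens as-is,
#'   so no linguistic resources are required.
#' @return a [tm_corpus][new_tm_corpus].
#' @export
preprocess_corpus <- function(docs, stopwords = default_stopwords(),
                              max_df = 0.8, min_count = 10, min_doc_len = 10,
                              lemmatizer = NULL) {
  docs <- tibble::as_tibble(docs)
  required <- c("text", "year", "label")
  missing_cols <- setdiff(required, names(docs))
  if (length(missing_cols) > 0)
    stop("missing corpus column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(docs) == 0) stop("empty corpus: no input documents")
  bad_year <- which(is.na(suppressWarnings(as.integer(docs$year))))
  if (length(bad_year) > 0)
    stop("unknown year for document(s): ", paste(utils::head(bad_year, 5), collapse = ", "))

  tokens <- if (is.list(docs$text)) docs$text else tokenize_text(docs$text)
  if (!is.null(lemmatizer)) tokens <- lapply(tokens, lemmatizer)
  tokens <- lapply(tokens, function(tk) tk[!tk %in% stopwords])

  n_docs <- length(tokens)
  # corpus-wide document frequency and total counts, per word
  per_doc_tab <- lapply(tokens, function(tk) table(tk))
  all_words <- unique(unlist(lapply(per_doc_tab, names), use.names = FALSE))
  if (length(all_words) == 0) stop("all documents removed: nothing survives filtering")
  df_count <- integer(length(all_words)); names(df_count) <- all_words
  tot_count <- integer(length(all_words)); names(tot_count) <- all_words
  for (tab in per_doc_tab) {
    w <- names(tab)
    df_count[w] <- df_count[w] + 1L
    tot_count[w] <- tot_count[w] + as.integer(tab)
  }
  keep <- df_count <= max_df * n_docs & tot_count >= min_count
  vocab <- sort(all_words[keep])
  if (length(vocab) == 0) stop("all documents removed: vocabulary empty after filtering")

  kept_tokens <- lapply(tokens, function(tk) tk[tk %in% vocab])
  doc_len <- vapply(kept_tokens, length, integer(1))
  survive <- doc_len >= min_doc_len
  if (!any(survive)) stop("all documents removed: every document shorter than min_doc_len")

  kept_tokens <- kept_tokens[survive]
  years_raw <- as.integer(docs$year)[survive]
  labels_raw <- as.character(docs$label)[survive]

  years <- sort(unique(years_raw))
  label_names <- sort(unique(labels_raw))
  slice <- match(years_raw, years)
  label <- match(labels_raw, label_names)

  # sparse triplet assembly
  i_idx <- rep.int(seq_along(kept_tokens), vapply(kept_tokens, length, integer(1)))
  j_idx <- match(unlist(kept_tokens, use.names = FALSE), vocab)
  counts <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = 1,
                                 dims = c(length(kept_tokens), length(vocab)))

  doc_ids <- if ("doc_id" %in% names(docs)) as.character(docs$doc_id)[survive] else
    sprintf("doc%06d", which(survive))
  meta <- tibble::tibble(doc_id = doc_ids, slice = slice, year = years_raw,
                         label = label)
  new_tm_corpus(counts, meta, vocab, label_names, years)
}

#' Stratified train/validation/test split of a corpus
#'
#' Partitions the documents of every time slice into train/validation/test
#' subsets with the given fractions (the defaults are the conventional
#' 85/5/10). The partition is disjoint and exhaustive within each slice and
#' deterministic given `seed`. A slice with fewer documents than there are
#' requested parts contributes all of its documents to the training split
#' (with a warning), so every non-empty slice is represented in training.
#'
#' @param corpus a [tm_corpus][new_tm_corpus].
#' @param fractions numeric length-3 vector `(train, valid, test)`, positive,
#'   summing to 1.
#' @param seed integer seed controlling the shuffling.
#' @return named list of three `tm_corpus` objects: `train`, `valid`, `test`.
#' @export
split_corpus <- function(corpus, fractions = c(0.85, 0.05, 0.10), seed = 1L) {
  stopifnot(length(fractions) == 3, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8)
  rng <- local_rng(seed)
  assign_split <- rep(1L, nrow(corpus$docs))
  small_slices <- integer(0)
  for (t in seq_along(corpus$years)) {
    idx <- which(corpus$docs$slice == t)
    n <- length(idx)
    if (n == 0) next
    if (n < 3) { small_slices <- c(small_slices, t); next }
    sizes <- diff(floor(cumsum(c(0, fractions)) * n + 1e-9))
    # every non-empty slice must feed the training split
    if (sizes[1] == 0) { k <- which.max(sizes); sizes[k] <- sizes[k] - 1L; sizes[1] <- 1L }
    perm <- idx[sample.int(n)]
    assign_split[perm] <- rep.int(1:3, sizes)
  }
  if (length(small_slices) > 0)
    warning("slice(s) with fewer documents than splits assigned wholly to training: ",
            paste(small_slices, collapse = ", "))
  list(train = subset_corpus(corpus, which(assign_split == 1L)),
       valid = subset_corpus(corpus, which(assign_split == 2L)),
       test  = subset_corpus(corpus, which(assign_split == 3L)))
}

#' Read a raw corpus file
#'
#' Reads documents from JSON-lines (one object per line with fields `text`,
#' `year`, `label`) or tab-separated (header `text`, `year`, `label`) files
#' into the tibble accepted by [preprocess_corpus()]. Malformed lines are
#' reported with their line numbers.
#'
#' @param path file path.
#' @param format `"jsonl"` or `"tsv"`.
#' @return tibble with columns `text`, `year`, `label`.
#' @export
read_corpus <- function(path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- vector("list", length(lines))
    bad <- integer(0)
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(e) NULL)
      if (is.null(rec) || !all(c("text", "year", "label") %in% names(rec))) {
        bad <- c(bad, i)
      } else {
        recs[[i]] <- tibble::tibble(text = as.character(rec$text),
                                    year = as.integer(rec$year),
                                    label = as.character(rec$label))
      }
    }
    if (length(bad) > 0)
      stop("malformed JSONL record(s) at line(s): ", paste(utils::head(bad, 10), collapse = ", "))
    dplyr::bind_rows(recs)
  } else {
    tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             quote = "", comment.char = "")
    missing_cols <- setdiff(c("text", "year", "label"), names(tab))
    if (length(missing_cols) > 0)
      stop("TSV is missing column(s): ", paste(missing_cols, collapse = ", "))
    tibble::tibble(text = as.character(tab$text), year = as.integer(tab$year),
                   label = as.character(tab$label))
  }
}

#' Write / read a corpus in sparse bag-of-words form
#'
#' The on-disk layout is plain text: `counts.mtx` (MatrixMarket sparse
#' counts, documents in rows), `vocabulary.txt` (one term per line, column
#' order) and `metadata.json` (slice years, label names, and the per-document
#' `doc_id`/`slice`/`year`/`label` table). `read_bow(write_bow(x))` restores
#' the corpus exactly.
#'
#' @param corpus a [tm_corpus][new_tm_corpus].
#' @param dir directory to create/fill.
#' @return `write_bow` returns `dir` invisibly; `read_bow` returns the
#'   `tm_corpus`.
#' @export
write_bow <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(corpus$counts, file.path(dir, "counts.mtx"))
  writeLines(corpus$vocabulary, file.path(dir, "vocabulary.txt"))
  meta <- list(format_version = 1L,
               years = corpus$years,
               label_names = corpus$label_names,
               docs = as.list(corpus$docs))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' @rdname write_bow
#' @export
read_bow <- function(dir) {
  for (f in c("counts.mtx", "vocabulary.txt", "metadata.json"))
    if (!file.exists(file.path(dir, f))) stop("BOW store is missing ", f)
  counts <- Matrix::readMM(file.path(dir, "counts.mtx"))
  vocab <- readLines(file.path(dir, "vocabulary.txt"))
  meta <- jsonlite::fromJSON(file.path(dir, "metadata.json"))
  if (ncol(counts) != length(vocab))
    stop("vocabulary/metadata mismatch: matrix has ", ncol(counts),
         " columns but vocabulary has ", length(vocab), " terms")
  docs <- tibble::tibble(doc_id = as.character(meta$docs$doc_id),
                         slice = as.integer(meta$docs$slice),
                         year = as.integer(meta$docs$year),
                         label = as.integer(meta$docs$label))
  if (nrow(docs) != nrow(counts))
    stop("vocabulary/metadata mismatch: metadata describes ", nrow(docs),
         " documents but matrix has ", nrow(counts), " rows")
  new_tm_corpus(counts, docs, vocab, as.character(meta$label_names),
                as.integer(meta$years))
}

#' Optional pretrained word embeddings
#'
#' Reads a whitespace-separated embedding table (first token the word, then L
#' floats per line, the layout used by common embedding releases) and returns
#' the L x V matrix aligned to `vocabulary`; words without a pretrained
#' vector are initialized from `N(0, init_sd^2)`.
#'
#' @param path embedding text file.
#' @param vocabulary character vector to align columns to.
#' @param init_sd standard deviation for missing words.
#' @param seed seed for the random fill-in.
#' @return numeric matrix, rows = embedding dimensions, columns = vocabulary.
#' @export
read_embeddings <- function(path, vocabulary, init_sd = 0.1, seed = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  words <- vapply(parts, `[[`, character(1), 1)
  L <- length(parts[[1]]) - 1L
  vecs <- vapply(parts, function(p) as.numeric(p[-1]), numeric(L))
  rng <- local_rng(seed)
  rho <- matrix(stats::rnorm(L * length(vocabulary), sd = init_sd), nrow = L)
  hit <- match(vocabulary, words)
  found <- which(!is.na(hit))
  if (length(found) > 0) rho[, found] <- vecs[, hit[found], drop = FALSE]
  colnames(rho) <- vocabulary
  rho
}
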