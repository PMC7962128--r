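#' Multi-label gait annotation
#'
#' Six binary flags: normal gait (NG), stroke gait (SG), and the four
#' stroke-gait abnormalities — drop foot (SGwDF), circumduction (SGwC),
#' hip hiking (SGwHH), back knee (SGwBK). Exactly one of NG/SG is set; a
#' normal gait carries no abnormality flags; a stroke gait may carry any
#' combination including none.
#'
#' @param ng,sg,sgw_df,sgw_c,sgw_hh,sgw_bk logical or 0/1 flags.
#' @return an object of class `gait_label` (named logical list).
#' @export
gait_label <- function(ng, sg, sgw_df = FALSE, sgw_c = FALSE,
                       sgw_hh = FALSE, sgw_bk = FALSE) {
  v <- vapply(list(ng, sg, sgw_df, sgw_c, sgw_hh, sgw_bk),
              function(x) as.logical(x)[1L], logical(1))
  if (anyNA(v)) stop_format("gait label flags must be TRUE/FALSE or 0/1")
  names(v) <- c("ng", "sg", "sgw_df", "sgw_c", "sgw_hh", "sgw_bk")
  if (v[["ng"]] + v[["sg"]] != 1L) {
    stop_format("exactly one of ng/sg must be set")
  }
  if (v[["ng"]] && any(v[3:6])) {
    stop_format("a normal gait cannot carry abnormality flags")
  }
  structure(as.list(v), class = "gait_label")
}

#' Encode a gait label into the network's two target vectors
#'
#' The detection head learns `[NG, SG]`; the classification head learns
#' `[SG, DF, C, HH, BK]` (a normal gait's classification target is all
#' zeros).
#'
#' @param label a [gait_label()].
#' @return list with numeric `detection` (length 2) and `classification`
#'   (length 5).
#' @seealso [decode_targets()] for the exact inverse.
#' @export
encode_targets <- function(label) {
  if (!inherits(label, "gait_label")) {
    stop_format("encode_targets expects a gait_label")
  }
  l <- vapply(label, as.numeric, numeric(1))
  list(detection = unname(l[c("ng", "sg")]),
       classification = unname(l[c("sg", "sgw_df", "sgw_c", "sgw_hh",
                                   "sgw_bk")]))
}

#' Decode target vectors back into a gait label
#'
#' @param detection numeric/binary length-2 vector `[NG, SG]`.
#' @param classification numeric/binary length-5 vector
#'   `[SG, DF, C, HH, BK]`.
#' @return a [gait_label()].
#' @export
decode_targets <- function(detection, classification) {
  stopifnot(length(detection) == 2L, length(classification) == 5L)
  gait_label(ng = detection[1] == 1, sg = detection[2] == 1,
             sgw_df = classification[2] == 1, sgw_c = classification[3] == 1,
             sgw_hh = classification[4] == 1, sgw_bk = classification[5] == 1)
}

#' Labelled dataset of normalized gait cycles
#'
#' @param cycles numeric matrix, one row per gait cycle (typically 100
#'   columns).
#' @param labels data.frame with columns `subject`, `leg`, `cycle_index`
#'   and the six 0/1 flags `ng`, `sg`, `sgw_df`, `sgw_c`, `sgw_hh`,
#'   `sgw_bk`; one row per cycle.
#' @return an object of class `gait_dataset`.
#' @export
gait_dataset <- function(cycles, labels) {
  cycles <- as.matrix(cycles)
  rownames(cycles) <- NULL
  need <- c("subject", "leg", "cycle_index", "ng", "sg", "sgw_df", "sgw_c",
            "sgw_hh", "sgw_bk")
  missing_cols <- setdiff(need, names(labels))
  if (length(missing_cols)) {
    stop_format("labels is missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  if (nrow(cycles) != nrow(labels)) {
    stop_format("cycles (%d rows) and labels (%d rows) must align",
                nrow(cycles), nrow(labels))
  }
  flags <- as.matrix(labels[, c("ng", "sg", "sgw_df", "sgw_c", "sgw_hh",
                                "sgw_bk")])
  if (!all(flags %in% c(0, 1)) || !all(labels$ng + labels$sg == 1) ||
      any(labels$ng == 1 & rowSums(flags[, 3:6, drop = FALSE]) > 0)) {
    stop_format("labels violate the gait-label invariants")
  }
  rownames(labels) <- NULL
  structure(list(cycles = cycles, labels = labels), class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat(sprintf("<gait_dataset> %d cycles x %d points; %d stroke, %d normal\n",
              nrow(x$cycles), ncol(x$cycles), sum(x$labels$sg),
              sum(x$labels$ng)))
  invisible(x)
}

#' Target matrices for a whole dataset
#'
#' @param dataset a [gait_dataset].
#' @return list with `detection` (n x 2) and `classification` (n x 5)
#'   numeric matrices, row-aligned with `dataset$cycles`.
#' @export
target_matrices <- function(dataset) {
  l <- dataset$labels
  list(
    detection = cbind(ng = l$ng, sg = l$sg),
    classification = cbind(sg = l$sg, sgw_df = l$sgw_df, sgw_c = l$sgw_c,
                           sgw_hh = l$sgw_hh, sgw_bk = l$sgw_bk)
  )
}

#' Stratified k-fold split of a labelled dataset
#'
#' Partitions cycle indices into `k` folds, stratified on the full
#' six-flag label combination so every fold sees every class in close to
#' its global proportion. If some combination has fewer than `k` members,
#' stratification falls back to the detection label (NG/SG) with a
#' warning. The split is an exact partition and is deterministic for a
#' fixed seed.
#'
#' Stratification operates on individual gait cycles, not subjects, so
#' cycles of one subject can appear in both training and validation folds;
#' see the package vignette for the leakage implications.
#'
#' @param dataset a [gait_dataset].
#' @param k number of folds (default 4).
#' @param seed RNG seed.
#' @return an object of class `fold_split`: list with `k`, `assignment`
#'   (integer fold id per cycle), `seed`.
#' @export
make_folds <- function(dataset, k = 4, seed = 0) {
  n <- nrow(dataset$cycles)
  if (k < 2 || k > n) {
    stop_format("k must be between 2 and the dataset size (%d), got %g",
                n, k)
  }
  l <- dataset$labels
  combo <- paste(l$ng, l$sg, l$sgw_df, l$sgw_c, l$sgw_hh, l$sgw_bk)
  if (min(table(combo)) < k) {
    warning("some label combinations have fewer than k members; ",
            "stratifying on the detection label only", call. = FALSE)
    combo <- as.character(l$sg)
  }
  assignment <- integer(n)
  local_seed(seed, {
    for (g in unique(combo)) {
      idx <- which(combo == g)
      idx <- idx[sample.int(length(idx))]
      # random fold-order rotation keeps rounding remainders from always
      # landing in fold 1
      folds <- rep_len(sample.int(k), length(idx))
      assignment[idx] <- folds
    }
  })
  structure(list(k = as.integer(k), assignment = assignment,
                 seed = seed), class = "fold_split")
}

#' Seeded shuffled mini-batches over training indices
#'
#' Every epoch visits each sample exactly once in a freshly seeded random
#' order; the final batch may be short.
#'
#' @param indices integer vector of sample indices to batch.
#' @param batch_size samples per batch (>= 1).
#' @param seed per-epoch shuffle seed.
#' @return list of integer index vectors.
#' @export
batches <- function(indices, batch_size, seed = 0) {
  if (batch_size < 1) stop_format("batch_size must be >= 1")
  n <- length(indices)
  if (n == 0L) return(list())
  shuffled <- local_seed(seed, indices[sample.int(n)])
  split(shuffled, ceiling(seq_len(n) / batch_size))
}

#' Write a labelled dataset as a cycles CSV plus a labels CSV
#'
#' @param dataset a [gait_dataset].
#' @param cycles_path,labels_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_dataset <- function(dataset, cycles_path, labels_path) {
  utils::write.csv(as.data.frame(dataset$cycles), cycles_path,
                   row.names = FALSE)
  utils::write.csv(dataset$labels, labels_path, row.names = FALSE)
  invisible(c(cycles_path, labels_path))
}

#' Read a labelled dataset written by [write_dataset()]
#'
#' @param cycles_path,labels_path CSV paths.
#' @return a [gait_dataset].
#' @export
read_dataset <- function(cycles_path, labels_path) {
  cycles <- as.matrix(utils::read.csv(cycles_path))
  labels <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  gait_dataset(cycles, labels)
}

#' Persist or load a fold assignment as JSON
#'
#' @param split a `fold_split`.
#' @param path JSON file path.
#' @return `write_fold_split`: the path, invisibly; `read_fold_split`:
#'   a `fold_split`.
#' @export
write_fold_split <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fold_split
#' @export
read_fold_split <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(k = as.integer(raw$k),
                 assignment = as.integer(raw$assignment),
                 seed = raw$seed), class = "fold_split")
}
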