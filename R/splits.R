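# Repeated stratified 70:15:15 train/validation/test splits.

# Integer apportionment by largest remainder: sizes sum to n exactly and
# each part is within one of n * ratio.
largest_remainder <- function(n, ratios) {
  raw <- n * ratios / sum(ratios)
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Repeated stratified random partitions
#'
#' Produces `n_repeats` independent random partitions of the cohort into
#' training, validation and test sets at the given ratios, stratified by
#' class: the apportionment is done per class by largest-remainder
#' rounding, so each partition's class fraction is within one patient of
#' the cohort fraction.
#'
#' @param labels class label per patient (any binary coding).
#' @param n_repeats number of independent partitions (default 100).
#' @param ratios train/validation/test proportions (default 70:15:15).
#' @param seed integer seed; the full list of partitions is reproducible.
#' @param min_class_size smallest per-class count accepted (default 10).
#' @return List of length `n_repeats`; each element has integer index
#'   vectors `train`, `validation`, `test` partitioning `seq_along(labels)`.
#' @examples
#' sp <- make_splits(rep(c(1, 0), c(32, 60)), n_repeats = 2, seed = 1)
#' lengths(sp[[1]])
#' @export
make_splits <- function(labels, n_repeats = 100L, ratios = c(0.70, 0.15, 0.15),
                        seed = 1L, min_class_size = 10L) {
  y <- as_binary_label(labels)
  cls <- split(seq_along(y), y)
  if (length(cls) < 2L || any(lengths(cls) < min_class_size))
    stop(sprintf("class too small to stratify: need >= %d patients per class",
                 min_class_size), call. = FALSE)
  if (length(ratios) != 3L || any(ratios <= 0))
    stop("`ratios` must be three positive proportions", call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) {
      parts <- list(train = integer(0), validation = integer(0),
                    test = integer(0))
      for (idx in cls) {
        sizes <- largest_remainder(length(idx), ratios)
        shuffled <- sample(idx)
        parts$train <- c(parts$train, shuffled[seq_len(sizes[1])])
        parts$validation <- c(parts$validation,
                              shuffled[sizes[1] + seq_len(sizes[2])])
        parts$test <- c(parts$test,
                        shuffled[sizes[1] + sizes[2] + seq_len(sizes[3])])
      }
      lapply(parts, sort)
    })
  })
}
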