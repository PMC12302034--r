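#' Split an image set into train and test partitions
#'
#' Produces a disjoint, exhaustive partition. With `stratified = TRUE`
#' (default) each class contributes `floor(n_class * train_frac)` images to
#' the training set, so the per-class training fraction deviates from
#' `train_frac` by less than one image; flooring also guarantees a non-empty
#' test set for any `train_frac < 1`.
#'
#' @param data A `labeled_image_set`.
#' @param train_frac Fraction of images for training, strictly in (0, 1).
#' @param seed RNG seed for the shuffle.
#' @param stratified Split within each class (default `TRUE`); every class
#'   must then have at least 2 members.
#' @return List with `train` and `test` `labeled_image_set`s.
#' @export
split_train_test <- function(data, train_frac = 0.7, seed = 1L,
                             stratified = TRUE) {
  stopifnot(inherits(data, "labeled_image_set"))
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must lie strictly between 0 and 1")
  }
  n <- length(data$images)
  if (n == 0L) stop("cannot split an empty image set")
  idx_train <- integer(0)
  with_seed(seed, {
    if (stratified) {
      for (k in sort(unique(data$labels))) {
        ik <- which(data$labels == k)
        if (length(ik) < 2L) {
          stop("stratified split needs at least 2 images per class; class ",
               data$class_names[k + 1L], " has ", length(ik))
        }
        ntr <- floor(length(ik) * train_frac)
        idx_train <- c(idx_train, sample(ik, ntr))
      }
    } else {
      idx_train <- sample.int(n, floor(n * train_frac))
    }
  })
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_len(n), idx_train)
  list(train = subset_image_set(data, idx_train),
       test = subset_image_set(data, idx_test))
}
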