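# Ablation variants: which components exist and which loss terms train them.
#
#   A     convolutional branch alone (supervised cross-entropy only)
#   B     plain transformer alone (single view, no cross-view fusion)
#   C     both branches, plain transformer, no heads (two cross-entropies)
#   D     both branches with multi-view encoding, no heads
#   E     D + ensemble classifier
#   F     D + fusion classifier (branch totals include the fusion-to-branch
#         transfer; no ensemble term)
#   G     D + ensemble + fusion classifiers
#   full  G trained with Mixup expansion
#   AFC1-3 are G with the paired shallow/middle/deep taps (convolutional
#   tap k with transformer view k); AFC3 equals the default pairing.

#' Build an ablation variant of the model
#'
#' @param name One of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`, `"F"`, `"G"`,
#'   `"full"`, `"AFC1"`, `"AFC2"`, `"AFC3"`.
#' @param cfg A [train_config()]; tap stages are overridden for the AFC
#'   variants.
#' @return An `ofml_model` whose `flags` encode the variant; [train()]
#'   honours the flags (Mixup only for `"full"`, loss terms per head).
#' @export
build_ablation_variant <- function(name, cfg) {
  stopifnot(inherits(cfg, "train_config"))
  name <- match.arg(name, c("A", "B", "C", "D", "E", "F", "G", "full",
                            "AFC1", "AFC2", "AFC3"))
  fl <- switch(name,
    A = model_flags(use_cnn = TRUE, use_mvt = FALSE, multi_view = FALSE,
                    use_ec = FALSE, use_afc = FALSE, use_mixup = FALSE),
    B = model_flags(use_cnn = FALSE, use_mvt = TRUE, multi_view = FALSE,
                    use_ec = FALSE, use_afc = FALSE, use_mixup = FALSE),
    C = model_flags(multi_view = FALSE, use_ec = FALSE, use_afc = FALSE,
                    use_mixup = FALSE),
    D = model_flags(use_ec = FALSE, use_afc = FALSE, use_mixup = FALSE),
    E = model_flags(use_ec = TRUE, use_afc = FALSE, use_mixup = FALSE),
    F = model_flags(use_ec = FALSE, use_afc = TRUE, use_mixup = FALSE),
    G = model_flags(use_mixup = FALSE),
    full = model_flags(),
    AFC1 = model_flags(use_ec = FALSE, use_afc = TRUE, use_mixup = FALSE),
    AFC2 = model_flags(use_ec = FALSE, use_afc = TRUE, use_mixup = FALSE),
    AFC3 = model_flags(use_ec = FALSE, use_afc = TRUE, use_mixup = FALSE))
  if (startsWith(name, "AFC")) {
    k <- as.integer(substring(name, 4L))
    cfg$cnn$tap_stage <- k
    cfg$mvt$tap_layer <- k
  }
  model <- build_model(cfg, fl)
  model$variant <- name
  model
}
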