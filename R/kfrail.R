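#' K-FRAIL score to frailty category
#'
#' Maps the 5-item K-FRAIL questionnaire score (Fatigue, Resistance,
#' Ambulation, Illnesses, Loss of weight; one point each) to the standard
#' three-level frailty category: 0 is robust, 1-2 prefrail, 3 or more frail.
#'
#' @param score integer vector of K-FRAIL scores in `[0, 5]`.
#' @return factor with levels `robust`, `prefrail`, `frail`.
#' @examples
#' kfrail_categorize(0:5)
#' @export
kfrail_categorize <- function(score) {
  if (any(is.na(score)) || any(score != as.integer(score)) ||
      any(score < 0) || any(score > 5)) {
    stop_domain("K-FRAIL scores must be integers in [0, 5]")
  }
  score <- as.integer(score)
  cat <- ifelse(score >= 3, "frail", ifelse(score >= 1, "prefrail", "robust"))
  factor(cat, levels = kfrail_levels())
}

kfrail_levels <- function() c("robust", "prefrail", "frail")

#' Binary frailty label
#'
#' Collapses the three frailty categories into the binary outcome used for
#' classification: robust (0) versus prefrail-or-frail (1). Prefrail
#' individuals already exhibit physiological deficits and are pooled with the
#' frail group as the positive class.
#'
#' @param category factor or character vector with values `robust`,
#'   `prefrail` or `frail`.
#' @return integer vector of 0/1 labels.
#' @examples
#' binary_label(kfrail_categorize(c(0, 2, 4)))
#' @export
binary_label <- function(category) {
  category <- as.character(category)
  if (!all(category %in% kfrail_levels())) {
    stop_domain("unknown frailty category; expected robust/prefrail/frail")
  }
  as.integer(category != "robust")
}

kfrail_item_names <- function() {
  c("item_fatigue", "item_resistance", "item_ambulation",
    "item_illnesses", "item_weight_loss")
}
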