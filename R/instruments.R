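#' Default scoring keys for the self-report instruments
#'
#' The Healthy Eating Quiz (HEQ) is a 70-item food-frequency
#' questionnaire rated 0-4 ("never" .. "5 or more times a week") across 8
#' food subgroups; the 51-item Three-Factor Eating Questionnaire (TFEQ)
#' yields cognitive restraint, disinhibition and hunger subscales from
#' dichotomously scored items.  The instruments' proprietary item keys
#' are not public, so the shipped keys are editable placeholders: items
#' are assigned round-robin to subgroups/subscales with unit weights and
#' no reverse keying.  Subscale-level simulation (see
#' [default_outcome_cells()]) is the default analysis path; item-level
#' scoring exists so real keys can be dropped in.
#'
#' @return A list with `heq` and `tfeq` key data.frames (columns `item`,
#'   `subscale`, `min`, `max`, `reverse`, `weight`).
#' @export
default_instrument_keys <- function() {
  heq_groups <- c("fruits", "vegetables", "meat_proteins",
                  "vegetarian_proteins", "grains", "water", "dairy",
                  "extras")
  heq <- data.frame(
    item = 1:70,
    subscale = rep(heq_groups, length.out = 70),
    min = 0, max = 4, reverse = FALSE, weight = 1,
    stringsAsFactors = FALSE
  )
  # TFEQ-51 subscale sizes: restraint 21, disinhibition 16, hunger 14.
  tfeq <- data.frame(
    item = 1:51,
    subscale = rep(c("cognitive_restraint", "disinhibition", "hunger"),
                   c(21, 16, 14)),
    min = 0, max = 1, reverse = FALSE, weight = 1,
    stringsAsFactors = FALSE
  )
  list(heq = heq, tfeq = tfeq)
}

#' Score an instrument's item responses against a key
#'
#' Keyed summation: each item contributes
#' `weight * response` (or `weight * (max + min - response)` when
#' reverse-keyed) to its subscale; subscale scores are sums and the total
#' is the sum of subscales.
#'
#' @param responses Integer vector of item responses, one per key row.
#' @param key A key data.frame (`item`, `subscale`, `min`, `max`,
#'   `reverse`, `weight`).
#' @return A list with `subscales` (named numeric) and `total`.
#' @export
score_instrument <- function(responses, key) {
  if (length(responses) != nrow(key)) {
    stop("expected ", nrow(key), " responses, got ", length(responses))
  }
  if (any(responses < key$min) || any(responses > key$max)) {
    stop("response out of the key's admissible range")
  }
  scored <- ifelse(key$reverse, key$max + key$min - responses, responses)
  scored <- scored * key$weight
  subscales <- tapply(scored, key$subscale, sum)
  list(subscales = c(subscales), total = sum(scored))
}

#' Score HEQ and TFEQ response vectors
#'
#' Convenience wrapper applying [score_instrument()] with the configured
#' keys: the HEQ total is the sum of its 8 food-subgroup scores; the TFEQ
#' yields the cognitive restraint, disinhibition and hunger subscales.
#'
#' @param heq_responses 70 HEQ item responses (0-4), or `NULL` to skip.
#' @param tfeq_responses 51 TFEQ item responses, or `NULL` to skip.
#' @param keys Instrument keys, default [default_instrument_keys()].
#' @return A list with `heq` and `tfeq` score lists (as from
#'   [score_instrument()]).
#' @export
score_instruments <- function(heq_responses = NULL, tfeq_responses = NULL,
                              keys = default_instrument_keys()) {
  out <- list()
  if (!is.null(heq_responses)) {
    out$heq <- score_instrument(heq_responses, keys$heq)
  }
  if (!is.null(tfeq_responses)) {
    out$tfeq <- score_instrument(tfeq_responses, keys$tfeq)
  }
  out
}
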