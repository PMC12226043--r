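# broom-style tidiers for fitted objects.

#' Tidy a Gaussian naive Bayes decoder
#'
#' @param x A `cap_nb` model.
#' @param ... Unused.
#' @return Tibble with one row per class x feature: `class`, `feature`,
#'   `mean`, `variance`, `prior`.
#' @export
tidy.cap_nb <- function(x, ...) {
  tidyr::expand_grid(class = x$classes, feature = x$features) |>
    dplyr::mutate(
      mean = as.vector(t(x$means)),
      variance = as.vector(t(x$vars)),
      prior = rep(x$priors, each = length(x$features)))
}

#' One-row summary of a Gaussian naive Bayes decoder
#'
#' @param x A `cap_nb` model.
#' @param ... Unused.
#' @return Tibble with `n_classes`, `n_features` and the class priors.
#' @export
glance.cap_nb <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes),
                 n_features = length(x$features),
                 prior_BL = x$priors[match("BL", x$classes)],
                 prior_TNF = x$priors[match("TNF", x$classes)],
                 prior_IL1B = x$priors[match("IL1B", x$classes)])
}

#' Tidy decoding results
#'
#' @param x A `cap_decode` object.
#' @param ... Unused.
#' @return The per-timepoint posterior tibble (`t_s`, `truth`, class
#'   posteriors, `decoded`).
#' @export
tidy.cap_decode <- function(x, ...) x$posteriors

#' One-row summary of decoding results
#'
#' @param x A `cap_decode` object.
#' @param ... Unused.
#' @return Tibble with per-class correct-assignment probabilities, overall
#'   hard accuracy and the number of decoded timepoints.
#' @export
glance.cap_decode <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    p_correct_BL = s$p_correct[s$class == "BL"],
    p_correct_TNF = s$p_correct[s$class == "TNF"],
    p_correct_IL1B = s$p_correct[s$class == "IL1B"],
    accuracy = sum(diag(x$confusion)) / sum(x$confusion),
    n_timepoints = nrow(x$posteriors))
}
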