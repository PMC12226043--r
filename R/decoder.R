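#' Build smoothed per-second decoder features
#'
#' Each unit's 1-s binned rate series is smoothed with a 30-point
#' Gaussian-weighted moving average (sigma = 5 points, i.e. the window spans
#' +-3 sigma; the kernel is normalized to unit sum and renormalized over the
#' valid support at the edges), and the true class — `BL`, or the cytokine
#' given first or second — is attached to every timepoint from the session
#' plan.
#'
#' @param rates Tibble of 1-s binned rates for one mouse's units
#'   (`unit_id`, `bin_start`, `rate`); all units must share the same grid.
#' @param plan The mouse's [session_plan()].
#' @param window Smoothing window length, points.
#' @return A `cap_features` tibble: `t_s`, `class` (factor
#'   `BL`/`TNF`/`IL1B`), and one `rate_<unit>` column per unit.
#' @export
build_features <- function(rates, plan, window = 30) {
  wide <- rates |>
    dplyr::select("unit_id", "bin_start", "rate") |>
    tidyr::pivot_wider(names_from = "unit_id", values_from = "rate",
                       names_prefix = "rate_") |>
    dplyr::arrange(.data$bin_start)
  if (anyNA(wide)) stop("units do not share a common 1-s time grid")
  t_s <- wide$bin_start
  sm <- lapply(wide[, -1, drop = FALSE], gauss_smooth, window = window)
  cyt <- period_cytokine(plan)
  cls <- as.character(period_at(t_s, plan))
  cls[cls == "C1"] <- cyt[["C1"]]
  cls[cls == "C2"] <- cyt[["C2"]]
  out <- tibble::tibble(
    t_s = t_s,
    class = factor(cls, levels = c("BL", "TNF", "IL1B")),
    tibble::as_tibble(sm))
  class(out) <- c("cap_features", class(out))
  out
}

# Gaussian-weighted moving average; kernel renormalized over the valid
# support near the edges so a constant series is left unchanged. An even
# window is centered with one extra backward point (weights symmetric).
gauss_smooth <- function(x, window = 30, sigma = window / 6) {
  n <- length(x)
  offs <- seq_len(window) - (window %/% 2 + 1L)
  k <- dnorm(seq_len(window) - (window + 1) / 2, sd = sigma)
  k <- k / sum(k)
  num <- numeric(n)
  den <- numeric(n)
  for (j in seq_len(window)) {
    src <- seq_len(n) + offs[j]
    ok <- src >= 1 & src <= n
    num[ok] <- num[ok] + k[j] * x[src[ok]]
    den[ok] <- den[ok] + k[j]
  }
  num / den
}

#' Stratified train/test split of decoder features
#'
#' Timepoints are split pseudo-randomly within each class, so both subsets
#' contain every class; the subsets are disjoint and reproducible by seed.
#'
#' @param features A `cap_features` tibble from [build_features()].
#' @param train_frac Fraction of each class assigned to training.
#' @param seed Integer seed.
#' @return List with `train` and `test` feature tibbles.
#' @export
split_train_test <- function(features, train_frac = 0.5, seed = 1L) {
  counts <- table(features$class)
  if (any(counts < 2)) {
    stop("every class needs at least 2 timepoints; got: ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  withr::with_seed(derive_seed(seed, 0L, salt = 9L), {
    idx <- unlist(lapply(levels(features$class), function(cl) {
      rows <- which(features$class == cl)
      n_tr <- min(max(1L, round(length(rows) * train_frac)),
                  length(rows) - 1L)
      sample(rows, n_tr)
    }))
  })
  list(train = features[sort(idx), ],
       test = features[-sort(idx), ])
}

#' Train a Gaussian naive Bayes decoder
#'
#' Fits per-class, per-feature Gaussian likelihoods (variances floored at
#' 1e-6 of the global feature variance to keep log-likelihoods finite) with
#' empirical class priors.
#'
#' @param train A `cap_features` tibble containing all three classes.
#' @return A `cap_nb` model (per-class means, variances, priors).
#' @export
train_nb <- function(train) {
  x <- as.matrix(dplyr::select(train, dplyr::starts_with("rate_")))
  cls <- droplevels(train$class)
  if (nlevels(cls) < 3) {
    stop("training data must contain all three classes; got ",
         paste(levels(cls), collapse = ", "))
  }
  global_var <- apply(x, 2, var)
  floor_var <- pmax(1e-6 * global_var, 1e-12)
  means <- t(sapply(levels(cls), function(l) colMeans(x[cls == l, , drop = FALSE])))
  vars <- t(sapply(levels(cls), function(l) {
    v <- apply(x[cls == l, , drop = FALSE], 2, var)
    pmax(v, floor_var)
  }))
  if (ncol(x) == 1) {  # sapply drops to vector for single feature
    means <- matrix(means, ncol = 1, dimnames = list(levels(cls), colnames(x)))
    vars <- matrix(vars, ncol = 1, dimnames = list(levels(cls), colnames(x)))
  }
  structure(list(
    classes = levels(cls),
    features = colnames(x),
    means = means, vars = vars,
    priors = as.numeric(table(cls)) / length(cls)
  ), class = "cap_nb")
}

#' @export
print.cap_nb <- function(x, ...) {
  cat(sprintf("<cap_nb> Gaussian naive Bayes: %d classes x %d features\n",
              length(x$classes), length(x$features)))
  invisible(x)
}

#' Decode immune state from features
#'
#' Gaussian naive Bayes posteriors are computed in log space and normalized
#' per timepoint; the decoded class is the posterior argmax (ties resolved
#' to the earlier class in the order BL < TNF < IL1B). The per-class
#' probability of correct assignment is the mean posterior mass assigned to
#' the true class over that class's timepoints; a hard accuracy (fraction of
#' argmax-correct timepoints) is reported alongside.
#'
#' @param model A `cap_nb` from [train_nb()].
#' @param test A `cap_features` tibble with matching feature columns.
#' @return A `cap_decode` object: `posteriors` (tibble `t_s`, `truth`,
#'   `p_BL`, `p_TNF`, `p_IL1B`, `decoded`), `summary` (per-class mean
#'   posterior on the truth and hard accuracy) and `confusion` (truth x
#'   decoded table).
#' @export
decode <- function(model, test) {
  feats <- dplyr::select(test, dplyr::starts_with("rate_"))
  if (!identical(colnames(feats), model$features)) {
    stop("feature columns do not match the trained model")
  }
  x <- as.matrix(feats)
  loglik <- sapply(seq_along(model$classes), function(ci) {
    rowSums(dnorm(x, mean = matrix(model$means[ci, ], nrow(x),
                                   ncol(x), byrow = TRUE),
                  sd = matrix(sqrt(model$vars[ci, ]), nrow(x),
                              ncol(x), byrow = TRUE), log = TRUE)) +
      log(model$priors[ci])
  })
  loglik <- matrix(loglik, nrow = nrow(x))
  m <- apply(loglik, 1, max)
  post <- exp(loglik - m)
  post <- post / rowSums(post)
  colnames(post) <- model$classes
  decoded <- factor(model$classes[max.col(post, ties.method = "first")],
                    levels = model$classes)
  posteriors <- tibble::tibble(
    t_s = test$t_s, truth = test$class,
    p_BL = post[, "BL"], p_TNF = post[, "TNF"], p_IL1B = post[, "IL1B"],
    decoded = decoded)
  truth_post <- post[cbind(seq_len(nrow(post)),
                           match(as.character(test$class), model$classes))]
  summary <- tibble::tibble(class = factor(model$classes,
                                           levels = model$classes)) |>
    dplyr::mutate(
      p_correct = vapply(.data$class, function(cl) {
        mean(truth_post[test$class == cl]) }, numeric(1)),
      accuracy = vapply(.data$class, function(cl) {
        mean(decoded[test$class == cl] == cl) }, numeric(1)),
      n = as.integer(table(test$class)[as.character(.data$class)]))
  structure(list(
    posteriors = posteriors,
    summary = summary,
    confusion = table(truth = test$class, decoded = decoded)
  ), class = "cap_decode")
}

#' @export
print.cap_decode <- function(x, ...) {
  cat("<cap_decode>", nrow(x$posteriors), "timepoints\n")
  print(x$summary)
  invisible(x)
}

#' Decode one mouse end to end
#'
#' Convenience chain within a single mouse: [build_features()] ->
#' [split_train_test()] -> [train_nb()] -> [decode()].
#'
#' @param rates 1-s binned rates for the mouse's included units.
#' @param plan The mouse's [session_plan()].
#' @param train_frac Training fraction.
#' @param seed Integer seed (split reproducibility).
#' @param window Smoothing window, points.
#' @return A `cap_decode` object.
#' @export
decode_mouse <- function(rates, plan, train_frac = 0.5, seed = 1L,
                         window = 30) {
  stopifnot(nrow(rates) > 0)
  features <- build_features(rates, plan, window = window)
  split <- split_train_test(features, train_frac = train_frac, seed = seed)
  model <- train_nb(split$train)
  decode(model, split$test)
}
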