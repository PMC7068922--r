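# Brennan-Prediger agreement coefficients for two rating passes.
#
# Unlike Cohen's kappa, chance agreement is fixed at 1/q (nominal) or at
# the mean of the agreement-weight matrix (ordinal), so the coefficient
# does not depend on the raters' marginal category frequencies.

#' Build a two-vector rating table
#'
#' Holds two ratings per item (two raters, or the two passes of an
#' intra-rater design) on a common category set. For ordinal scales the
#' category order is the order of `categories`.
#'
#' @param rating_1,rating_2 Vectors of ratings, one per item.
#' @param categories Category labels; defaults to the sorted union of the
#'   observed ratings. Supply explicitly when unobserved categories exist
#'   (q enters the chance-agreement term).
#' @param scale `"nominal"` or `"ordinal"`.
#' @return A `rating_table` object.
#' @export
rating_table <- function(rating_1, rating_2, categories = NULL,
                         scale = c("nominal", "ordinal")) {
  scale <- match.arg(scale)
  rating_1 <- as.character(rating_1)
  rating_2 <- as.character(rating_2)
  if (length(rating_1) != length(rating_2)) {
    abort_validation("rating vectors must have one rating per item")
  }
  if (length(rating_1) == 0L) abort_validation("empty rating table")
  if (anyNA(rating_1) || anyNA(rating_2)) {
    abort_validation("ratings contain NA")
  }
  if (is.null(categories)) {
    categories <- sort(unique(c(rating_1, rating_2)))
  }
  categories <- as.character(categories)
  if (anyDuplicated(categories)) abort_validation("duplicate categories")
  if (length(categories) < 2L) abort_validation("need q >= 2 categories")
  bad <- setdiff(unique(c(rating_1, rating_2)), categories)
  if (length(bad) > 0L) {
    abort_validation(paste0("rating(s) outside the category set: ",
                            paste(bad, collapse = ", ")))
  }
  structure(list(rating_1 = rating_1, rating_2 = rating_2,
                 categories = categories, scale = scale),
            class = "rating_table")
}

#' Brennan-Prediger nominal kappa
#'
#' \eqn{K = (p_o - 1/q) / (1 - 1/q)} with \eqn{p_o} the observed
#' exact-agreement proportion and q the category count. Ranges from
#' \eqn{-1/(q-1)} to 1; invariant under permutation of category labels.
#'
#' @param table A [rating_table()] with `scale = "nominal"`.
#' @return The kappa coefficient.
#' @export
nominal_kappa <- function(table) {
  stopifnot(inherits(table, "rating_table"))
  if (table$scale != "nominal") {
    abort_validation("nominal_kappa requires a nominal rating table")
  }
  q <- length(table$categories)
  p_o <- mean(table$rating_1 == table$rating_2)
  (p_o - 1 / q) / (1 - 1 / q)
}

# Agreement-weight matrix: w_kl = 1 - (|k - l| / (q - 1))^s.
.agreement_weights <- function(q, scheme) {
  s <- switch(scheme, linear = 1, quadratic = 2,
              abort_validation("scheme must be 'linear' or 'quadratic'"))
  d <- abs(outer(seq_len(q), seq_len(q), "-"))
  1 - (d / (q - 1))^s
}

#' Brennan-Prediger weighted (ordinal) kappa
#'
#' \eqn{K_w = (p_o^{(w)} - p_e^{(w)}) / (1 - p_e^{(w)})} with partial
#' agreement credit \eqn{w_{kl} = 1 - (|k - l| / (q - 1))^s} (s = 1 linear,
#' s = 2 quadratic) and chance term \eqn{p_e^{(w)} = \sum_{kl} w_{kl}/q^2}.
#' With the identity weight matrix this reduces exactly to
#' [nominal_kappa()].
#'
#' @param table A [rating_table()] with `scale = "ordinal"` (category order
#'   taken from the table).
#' @param scheme `"linear"` (default) or `"quadratic"`.
#' @param weights Optional explicit q x q agreement-weight matrix
#'   overriding `scheme` (diagonal must be 1).
#' @return The weighted kappa coefficient.
#' @export
weighted_kappa <- function(table, scheme = c("linear", "quadratic"),
                           weights = NULL) {
  stopifnot(inherits(table, "rating_table"))
  if (table$scale != "ordinal" && is.null(weights)) {
    abort_validation("weighted_kappa requires an ordinal rating table")
  }
  q <- length(table$categories)
  W <- if (is.null(weights)) {
    .agreement_weights(q, match.arg(scheme))
  } else {
    if (!is.matrix(weights) || any(dim(weights) != q)) {
      abort_validation("weights must be a q x q matrix")
    }
    weights
  }
  i1 <- match(table$rating_1, table$categories)
  i2 <- match(table$rating_2, table$categories)
  p_o <- mean(W[cbind(i1, i2)])
  p_e <- sum(W) / q^2
  (p_o - p_e) / (1 - p_e)
}

#' Landis-Koch qualitative agreement label
#'
#' Maps a kappa value to the conventional strength-of-agreement bands:
#' below 0 "poor"; 0 to 0.20 "slight"; above 0.20 to 0.40 "fair"; above
#' 0.40 to 0.60 "moderate"; above 0.60 to 0.80 "substantial"; above 0.80
#' to 1 "almost perfect".
#'
#' @param K Kappa value (must not exceed 1).
#' @return Character label.
#' @export
landis_koch <- function(K) {
  if (any(K > 1 + 1e-12)) abort_validation("kappa cannot exceed 1")
  vapply(K, function(k) {
    if (k < 0) "poor"
    else if (k <= 0.20) "slight"
    else if (k <= 0.40) "fair"
    else if (k <= 0.60) "moderate"
    else if (k <= 0.80) "substantial"
    else "almost perfect"
  }, character(1))
}

#' Full agreement report for one rating table
#'
#' Computes the appropriate Brennan-Prediger coefficient for the table's
#' scale together with its observed and chance agreement and the
#' Landis-Koch label.
#'
#' @param table A [rating_table()].
#' @param scheme Ordinal weighting scheme, `"linear"` or `"quadratic"`
#'   (ignored for nominal tables).
#' @return List with `kappa`, `p_o`, `p_e`, `scale`, `scheme`, `label`.
#' @export
agreement_report <- function(table, scheme = c("linear", "quadratic")) {
  stopifnot(inherits(table, "rating_table"))
  scheme <- match.arg(scheme)
  q <- length(table$categories)
  if (table$scale == "nominal") {
    p_o <- mean(table$rating_1 == table$rating_2)
    p_e <- 1 / q
    K <- nominal_kappa(table)
    scheme <- "unweighted"
  } else {
    W <- .agreement_weights(q, scheme)
    i1 <- match(table$rating_1, table$categories)
    i2 <- match(table$rating_2, table$categories)
    p_o <- mean(W[cbind(i1, i2)])
    p_e <- sum(W) / q^2
    K <- weighted_kappa(table, scheme)
  }
  list(kappa = K, p_o = p_o, p_e = p_e, scale = table$scale,
       scheme = scheme, label = landis_koch(K))
}

#' Pairwise kappas for more than two raters
#'
#' Computes the Brennan-Prediger coefficient for every rater pair and
#' summarizes multi-rater agreement as their mean (reported per pair as
#' well).
#'
#' @param ratings Named list of rating vectors, one per rater, aligned on
#'   items.
#' @param categories Category labels shared by all raters.
#' @param scale `"nominal"` or `"ordinal"`.
#' @param scheme Ordinal weighting scheme.
#' @return List with `pairwise` (data frame: rater_1, rater_2, kappa,
#'   label) and `mean_kappa` with its `label`.
#' @export
multi_rater_kappa <- function(ratings, categories = NULL,
                              scale = c("nominal", "ordinal"),
                              scheme = c("linear", "quadratic")) {
  scale <- match.arg(scale)
  scheme <- match.arg(scheme)
  if (length(ratings) < 2L) abort_validation("need at least two raters")
  if (is.null(names(ratings))) {
    names(ratings) <- paste0("R", seq_along(ratings))
  }
  prs <- combn(length(ratings), 2)
  kap <- apply(prs, 2, function(p) {
    tab <- rating_table(ratings[[p[1]]], ratings[[p[2]]],
                        categories = categories, scale = scale)
    if (scale == "nominal") nominal_kappa(tab) else weighted_kappa(tab, scheme)
  })
  pairwise <- data.frame(rater_1 = names(ratings)[prs[1, ]],
                         rater_2 = names(ratings)[prs[2, ]],
                         kappa = as.numeric(kap),
                         label = landis_koch(as.numeric(kap)),
                         stringsAsFactors = FALSE)
  mk <- mean(kap)
  list(pairwise = pairwise, mean_kappa = mk, label = landis_koch(mk))
}
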