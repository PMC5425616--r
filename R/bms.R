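## Random-effects Bayesian model selection: variational Dirichlet estimate
## of model frequencies, exceedance probabilities by Dirichlet sampling, and
## protection via the Bayes omnibus risk.

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

#' Random-effects Bayesian model selection
#'
#' Given a subjects x models matrix of log marginal likelihoods, estimates
#' the population frequency of each model with the variational Dirichlet
#' scheme, computes exceedance probabilities (the probability that a model
#' is the most frequent) by sampling from the Dirichlet posterior, and
#' protects them against the null hypothesis of equal frequencies via the
#' Bayes omnibus risk: `pxp = (1 - bor) * ep + bor / K`. An optional family
#' partition aggregates member frequencies and exceedance mass per family.
#'
#' @param lme Numeric matrix, one row per subject, one column per model;
#'   all entries finite.
#' @param families Optional list of integer/character vectors partitioning
#'   the model columns into families.
#' @param alpha0 Dirichlet prior count per model (default 1).
#' @param n_samples Dirichlet samples for the exceedance probabilities.
#' @param max_iter,tol Variational iteration controls.
#' @param seed Optional integer seed for the Dirichlet sampling.
#' @return A list of class `bms_result`: `alpha` (posterior Dirichlet
#'   counts), `frequencies` (their expectations), `assignments` (subject x
#'   model responsibilities), `ep` (exceedance), `bor`, `pxp` (protected
#'   exceedance), and when `families` is given, `family_frequencies`,
#'   `family_ep`, `family_pxp`.
#' @export
#' @examples
#' lme <- cbind(a = c(0, 0, 5, 6), b = c(4, 3, 0, 0))
#' rfx_bms(lme, seed = 1)$frequencies
rfx_bms <- function(lme, families = NULL, alpha0 = 1, n_samples = 1e6,
                    max_iter = 200, tol = 1e-8, seed = NULL) {
  lme <- as.matrix(lme)
  if (any(!is.finite(lme)))
    stop("log marginal likelihoods must be finite", call. = FALSE)
  n <- nrow(lme)
  k <- ncol(lme)
  if (k < 2) stop("need at least two models", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  model_names <- colnames(lme)
  if (is.null(model_names)) model_names <- paste0("m", seq_len(k))

  alpha <- rep(alpha0, k)
  beta <- matrix(1 / k, n, k)
  for (it in seq_len(max_iter)) {
    elog_r <- digamma(alpha) - digamma(sum(alpha))
    lb <- sweep(lme, 2, elog_r, "+")
    lb <- lb - apply(lb, 1, max)
    beta_new <- exp(lb) / rowSums(exp(lb))
    alpha_new <- alpha0 + colSums(beta_new)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      beta <- beta_new
      break
    }
    alpha <- alpha_new
    beta <- beta_new
  }
  freq <- alpha / sum(alpha)

  # exceedance probabilities by Dirichlet sampling
  draws <- .rdirichlet(n_samples, alpha)
  winner <- max.col(draws, ties.method = "first")
  ep <- tabulate(winner, nbins = k) / n_samples

  # Bayes omnibus risk: F0 (equal frequencies) vs F1 (variational bound)
  f0 <- sum(apply(lme, 1, .logsumexp) - log(k))
  elog_r <- digamma(alpha) - digamma(sum(alpha))
  lbeta0 <- sum(lgamma(rep(alpha0, k))) - lgamma(k * alpha0)
  lbeta1 <- sum(lgamma(alpha)) - lgamma(sum(alpha))
  bl <- beta * log(pmax(beta, 1e-300))
  f1 <- sum(beta * lme) + sum(sweep(beta, 2, elog_r, "*")) - sum(bl) +
    sum((alpha0 - alpha) * elog_r) + lbeta1 - lbeta0
  bor <- 1 / (1 + exp(f1 - f0))
  pxp <- (1 - bor) * ep + bor / k

  out <- list(alpha = stats::setNames(alpha, model_names),
              frequencies = stats::setNames(freq, model_names),
              assignments = beta, ep = stats::setNames(ep, model_names),
              bor = bor, pxp = stats::setNames(pxp, model_names))

  if (!is.null(families)) {
    fam_idx <- lapply(families, function(f) {
      if (is.character(f)) match(f, model_names) else as.integer(f)
    })
    if (anyNA(unlist(fam_idx)) ||
        !setequal(unlist(fam_idx), seq_len(k)))
      stop("families must partition the model columns", call. = FALSE)
    nf <- length(fam_idx)
    fam_names <- names(families)
    if (is.null(fam_names)) fam_names <- paste0("family", seq_len(nf))
    fam_freq <- vapply(fam_idx, function(ix) sum(freq[ix]), numeric(1))
    fam_draws <- vapply(fam_idx, function(ix)
      rowSums(draws[, ix, drop = FALSE]), numeric(n_samples))
    fam_winner <- max.col(fam_draws, ties.method = "first")
    fam_ep <- tabulate(fam_winner, nbins = nf) / n_samples
    out$family_frequencies <- stats::setNames(fam_freq, fam_names)
    out$family_ep <- stats::setNames(fam_ep, fam_names)
    out$family_pxp <- stats::setNames((1 - bor) * fam_ep + bor / nf,
                                      fam_names)
  }
  class(out) <- "bms_result"
  out
}

#' @export
print.bms_result <- function(x, ...) {
  cat("Random-effects BMS over", length(x$frequencies), "models\n")
  tab <- rbind(frequency = x$frequencies, exceedance = x$ep,
               protected = x$pxp)
  print(round(tab, 4))
  cat("Bayes omnibus risk:", signif(x$bor, 4), "\n")
  if (!is.null(x$family_frequencies)) {
    cat("family frequencies:",
        paste(names(x$family_frequencies),
              round(x$family_frequencies, 4), collapse = "; "), "\n")
    cat("family protected exceedance:",
        paste(names(x$family_pxp), round(x$family_pxp, 4),
              collapse = "; "), "\n")
  }
  invisible(x)
}
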