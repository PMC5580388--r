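# Mixed-model fitting and information-theoretic model comparison.

#' Small-sample corrected Akaike information criterion
#'
#' \deqn{AICc = -2 \log L + 2k + 2k(k+1)/(n-k-1)}
#'
#' @param loglik maximised log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations; must exceed `k + 1`.
#' @return the AICc value.
#' @examples
#' aicc(-47, 3, 10)  # 104
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' Relative support of each candidate model,
#' \eqn{w_m = \exp(-\Delta_m/2) / \sum_j \exp(-\Delta_j/2)} with
#' \eqn{\Delta_m} the AICc difference to the best candidate. Invariant to
#' adding a constant to all log-likelihoods.
#'
#' @param aicc_values numeric vector of AICc values.
#' @return numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

# Squeeze a (0,1]-bounded response off the boundaries (standard transform
# for beta-family responses that can hit exactly 0 or 1).
.squeeze01 <- function(y) {
  n <- length(y)
  (y * (n - 1) + 0.5) / n
}

#' Fit a mixed model for one response
#'
#' Thin, deterministic wrapper around the fitting engines used throughout
#' the pipeline: gaussian responses use a linear mixed model
#' ([lme4::lmer()], maximum likelihood), gamma and beta responses use
#' [glmmTMB::glmmTMB()]. All models carry a random intercept per grouping
#' factor (frog) to account for repeated trajectories of the same
#' individuals.
#'
#' The gamma family defaults to the log link (the natural choice for a
#' strictly positive response); requesting the logit link for a gamma
#' response emits a warning and falls back to the log link. Beta responses
#' may include exact 1s (a perfectly straight trajectory), so they are
#' squeezed off the boundary with `y' = (y (n-1) + 0.5) / n` before fitting
#' (`squeeze = FALSE` disables this for responses known to be interior).
#'
#' @param response name of the response column.
#' @param fixed character vector of fixed-effect term names (empty = null
#'   model, intercept only).
#' @param data observation data frame.
#' @param family `"gaussian"`, `"gamma"` or `"beta"`.
#' @param link link function; defaults to identity / log / logit
#'   respectively.
#' @param random name of the random-intercept grouping factor.
#' @param squeeze apply the boundary squeeze to beta responses.
#' @return a `frog_model_fit`: list with `formula`, `family`, `link`,
#'   `terms`, `coefficients` (term, estimate, se), `loglik`, `k`, `n`,
#'   `aicc`, `converged`, `singular` and the underlying `fit` object.
#' @export
fit_mixed_model <- function(response, fixed = character(0), data,
                            family = c("gaussian", "gamma", "beta"),
                            link = NULL, random = "frog_id", squeeze = TRUE) {
  family <- match.arg(family)
  if (!random %in% names(data)) {
    stop("random-effect grouping column '", random, "' not in data",
         call. = FALSE)
  }
  if (length(unique(data[[random]])) < 2) {
    stop("random intercept needs at least 2 groups", call. = FALSE)
  }
  rhs <- paste(c(if (length(fixed)) fixed else "1",
                 sprintf("(1 | %s)", random)), collapse = " + ")
  fml <- as.formula(paste(response, "~", rhs))
  y <- data[[response]]
  if (family == "gamma" && any(y <= 0)) {
    stop("gamma family requires a strictly positive response", call. = FALSE)
  }
  if (family == "beta") {
    if (any(y <= 0 | y > 1)) {
      stop("beta family requires a response in (0, 1]", call. = FALSE)
    }
    if (squeeze) {
      data[[response]] <- .squeeze01(y)
    } else if (any(y >= 1)) {
      stop("boundary values present; use squeeze = TRUE", call. = FALSE)
    }
  }
  if (family != "gaussian" && sd(y) == 0) {
    # degenerate: with a constant response the likelihood is unbounded in
    # the dispersion and no MLE exists, but the mean profile is flat at the
    # constant; return the analytic limit, flagged and kept out of selection
    linkfun <- switch(family,
                      gamma = stats::Gamma(link = link %||% "log")$linkfun,
                      beta = stats::qlogis)
    terms_all <- c("(Intercept)", fixed)
    return(structure(
      list(formula = deparse(fml), family = family,
           link = link %||% if (family == "beta") "logit" else "log",
           terms = fixed,
           coefficients = data.frame(
             term = terms_all,
             estimate = c(linkfun(y[1]), rep(0, length(fixed))),
             se = NA_real_, stringsAsFactors = FALSE),
           loglik = Inf, k = NA_integer_, n = nrow(data), aicc = NA_real_,
           converged = FALSE, singular = TRUE, fit = NULL),
      class = "frog_model_fit"))
  }
  ctrl <- glmmTMB::glmmTMBControl()
  # deterministic start: intercept at the null-model estimate, slopes at 0
  n_beta <- 1 + length(fixed)
  start_at_null <- function(linkfun) {
    list(beta = c(linkfun(mean(data[[response]])), rep(0, n_beta - 1)))
  }
  fit <- switch(
    family,
    gaussian = {
      link <- link %||% "identity"
      if (link != "identity") stop("gaussian fits use the identity link",
                                   call. = FALSE)
      lme4::lmer(fml, data = data, REML = FALSE)
    },
    gamma = {
      link <- link %||% "log"
      if (link == "logit") {
        warning("logit link is nonstandard for a gamma response; using log")
        link <- "log"
      }
      fam <- stats::Gamma(link = link)
      tryCatch(
        glmmTMB::glmmTMB(fml, data = data, family = fam, control = ctrl,
                         start = start_at_null(fam$linkfun)),
        error = function(e)   # e.g. factor terms widen the design matrix
          glmmTMB::glmmTMB(fml, data = data, family = fam, control = ctrl)
      )
    },
    beta = {
      link <- link %||% "logit"
      fam <- glmmTMB::beta_family(link = link)
      tryCatch(
        glmmTMB::glmmTMB(fml, data = data, family = fam, control = ctrl,
                         start = start_at_null(fam$linkfun)),
        error = function(e)
          glmmTMB::glmmTMB(fml, data = data, family = fam, control = ctrl)
      )
    }
  )
  ll <- logLik(fit)
  est <- if (inherits(fit, "glmmTMB")) glmmTMB::fixef(fit)$cond
         else lme4::fixef(fit)
  se <- if (inherits(fit, "glmmTMB")) {
    sqrt(diag(vcov(fit)$cond))
  } else sqrt(diag(as.matrix(vcov(fit))))
  converged <- if (inherits(fit, "glmmTMB")) {
    isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
  } else {
    length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0 ||
      lme4::isSingular(fit)  # singular fits are retained, not failures
  }
  singular <- if (inherits(fit, "glmmTMB")) {
    vc <- glmmTMB::VarCorr(fit)$cond
    any(vapply(vc, function(m) any(diag(m) < 1e-8), logical(1)))
  } else lme4::isSingular(fit)
  n <- nrow(data)
  k <- attr(ll, "df")
  structure(
    list(formula = deparse(fml), family = family, link = link,
         terms = fixed,
         coefficients = data.frame(term = names(est), estimate = unname(est),
                                   se = unname(se), stringsAsFactors = FALSE),
         loglik = as.numeric(ll), k = k, n = n,
         aicc = aicc(as.numeric(ll), k, n),
         converged = converged, singular = singular, fit = fit),
    class = "frog_model_fit"
  )
}

#' @export
print.frog_model_fit <- function(x, ...) {
  cat(sprintf("<%s %s model> %s\n  logLik = %.3f, k = %d, n = %d, AICc = %.3f%s\n",
              x$family, x$link, x$formula, x$loglik, x$k, x$n, x$aicc,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Compare a full model against its null model
#'
#' Reports \eqn{\Delta AICc = AICc(null) - AICc(full)}. The full model is
#' supported only when it beats the null by more than 2 AICc units;
#' otherwise the variation is not explained better by the full model and the
#' null is retained.
#'
#' @param full,null `frog_model_fit` objects fitted to the same data.
#' @return list with `delta_aicc` and `verdict`
#'   (`"full_supported"` / `"null_supported"`).
#' @export
compare_to_null <- function(full, null) {
  if (full$n != null$n) {
    stop("full and null models were fitted to different n", call. = FALSE)
  }
  delta <- null$aicc - full$aicc
  list(delta_aicc = delta,
       verdict = if (delta > 2) "full_supported" else "null_supported")
}

#' All-subset model selection with model averaging
#'
#' Fits every subset of the candidate fixed-effect terms (always including
#' the random intercept), ranks the fits by AICc, retains the candidates
#' within 2 AICc units of the best one, and model-averages the coefficients
#' over that subset with Akaike weights renormalised within the subset. The
#' default full average substitutes 0 for terms absent from a model; the
#' conditional (natural) average over only the models containing each term
#' is also reported. Candidates that fail to converge are dropped with a
#' warning.
#'
#' @inheritParams fit_mixed_model
#' @param candidate_terms character vector of candidate fixed-effect terms
#'   (at most 20).
#' @param ... further arguments passed to [fit_mixed_model()].
#' @return a `frog_selection`: list with the ranked selection `table`
#'   (formula, k, n, loglik, aicc, delta, weight, in_subset), the fitted
#'   models (`fits`, AICc order), and `averaged` (term, estimate_full,
#'   estimate_conditional, weight_sum).
#' @export
all_subset_selection <- function(response, candidate_terms, data,
                                 family = "gaussian", random = "frog_id",
                                 ...) {
  p <- length(candidate_terms)
  if (p > 20) stop("more than 20 candidate terms (2^k model explosion)",
                   call. = FALSE)
  subsets <- lapply(0:(2^p - 1), function(mask) {
    candidate_terms[bitwAnd(mask, 2^(seq_len(p) - 1)) > 0]
  })
  fits <- lapply(subsets, function(tr) {
    tryCatch(fit_mixed_model(response, tr, data, family = family,
                             random = random, ...),
             error = function(e) NULL)
  })
  failed <- vapply(fits, function(f) is.null(f) || !f$converged, logical(1))
  if (any(failed)) {
    warning(sprintf("%d candidate model(s) failed to converge and were excluded",
                    sum(failed)))
  }
  fits <- fits[!failed]
  if (!length(fits)) stop("no candidate model converged", call. = FALSE)
  a <- vapply(fits, function(f) f$aicc, numeric(1))
  ord <- order(a)
  fits <- fits[ord]; a <- a[ord]
  delta <- a - a[1]
  w <- akaike_weights(a)
  in_subset <- delta <= 2
  tab <- data.frame(
    formula = vapply(fits, function(f) f$formula, character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    n = vapply(fits, function(f) f$n, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aicc = a, delta = delta, weight = w, in_subset = in_subset,
    stringsAsFactors = FALSE
  )
  sub <- fits[in_subset]
  wsub <- w[in_subset] / sum(w[in_subset])
  terms_union <- unique(unlist(lapply(sub, function(f) f$coefficients$term)))
  averaged <- do.call(rbind, lapply(terms_union, function(tm) {
    est <- vapply(sub, function(f) {
      i <- match(tm, f$coefficients$term)
      if (is.na(i)) 0 else f$coefficients$estimate[i]
    }, numeric(1))
    present <- vapply(sub, function(f) tm %in% f$coefficients$term, logical(1))
    data.frame(term = tm,
               estimate_full = sum(wsub * est),
               estimate_conditional = if (any(present))
                 sum(wsub[present] * est[present]) / sum(wsub[present])
               else NA_real_,
               weight_sum = sum(wsub[present]),
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, fits = fits, averaged = averaged,
                 response = response, family = family),
            class = "frog_selection")
}

#' @export
print.frog_selection <- function(x, ...) {
  cat(sprintf("All-subset selection for '%s' (%s family): %d candidates, %d in the dAICc <= 2 subset\n",
              x$response, x$family, nrow(x$table), sum(x$table$in_subset)))
  print(x$table[, c("formula", "k", "aicc", "delta", "weight")], digits = 4)
  invisible(x)
}
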