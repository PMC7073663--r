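#' Configuration for per-arm Bayesian model averaging
#'
#' @param alpha Zellner-Siow prior scale (default 1).
#' @param model_prior `"uniform"` over the 2^p model space (default) or
#'   `"beta_binomial"` (Beta-Binomial(1,1) on model size).
#' @param n_models sampling budget: number of distinct models scored by
#'   [mcmc_bas()] (default 30000).
#' @param mcmc_iterations Metropolis-Hastings steps in the exploration
#'   phase; default: equal to `n_models`.
#' @param seed integer seed for the sampler.
#' @param enumeration_limit largest p for exhaustive enumeration
#'   (default 20).
#' @return object of class `bma_config`.
#' @export
bma_config <- function(alpha = 1, model_prior = c("uniform", "beta_binomial"),
                       n_models = 30000L, mcmc_iterations = NULL, seed = 1L,
                       enumeration_limit = 20L) {
  stopifnot(alpha > 0, n_models >= 1)
  structure(list(alpha = alpha, model_prior = match.arg(model_prior),
                 n_models = as.integer(n_models),
                 mcmc_iterations = if (is.null(mcmc_iterations)) NULL else as.integer(mcmc_iterations),
                 seed = as.integer(seed),
                 enumeration_limit = as.integer(enumeration_limit)),
            class = "bma_config")
}

resolve_design <- function(x, y) {
  if (inherits(x, "coded_matrix")) {
    if (is.null(y)) y <- x$outcome
    x <- x$x
  }
  stopifnot(is.matrix(x), is.numeric(y), nrow(x) == length(y), !anyNA(y), !anyNA(x))
  list(x = x, y = as.numeric(y))
}

# centered sufficient statistics; every model's R^2 comes from one
# Cholesky solve on a subset of the cross-product matrix
make_r2_fun <- function(x, y) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  xtx <- crossprod(xc)
  xty <- drop(crossprod(xc, yc))
  yty <- sum(yc^2)
  function(idx) {
    if (!length(idx)) return(0)
    a <- xtx[idx, idx, drop = FALSE]
    b <- xty[idx]
    beta <- tryCatch(chol2inv(chol(a)) %*% b,
                     error = function(e) {
                       # exactly collinear subset: minimum-norm solution
                       sv <- svd(a)
                       pos <- sv$d > max(sv$d) * 1e-10
                       sv$v[, pos, drop = FALSE] %*%
                         (crossprod(sv$u[, pos, drop = FALSE], b) / sv$d[pos])
                     })
    r2 <- sum(b * beta) / yty
    min(max(r2, 0), 1 - 1e-12)
  }
}

model_log_prior <- function(p_gamma, p, model_prior) {
  if (model_prior == "uniform") rep(-p * log(2), length(p_gamma))
  else -log(p + 1) - lchoose(p, p_gamma)
}

# assemble a bma_result from scored models (shared by both methods)
finalize_bma <- function(gamma, r2, lml, columns, n, config, method,
                         n_skipped = 0L, note = NULL, arm = NULL) {
  p <- length(columns)
  p_gamma <- as.integer(rowSums(gamma))
  log_prior <- model_log_prior(p_gamma, p, config$model_prior)
  w <- lml + log_prior
  w[!is.finite(lml)] <- -Inf
  m <- max(w)
  post <- exp(w - m)
  post <- post / sum(post)
  pip <- drop(crossprod(gamma, post))
  names(pip) <- columns
  key <- apply(gamma, 1L, paste, collapse = "")
  ord <- order(-post, p_gamma, key)
  structure(list(
    arm = arm, columns = columns, n = n,
    gamma = gamma[ord, , drop = FALSE],
    p_gamma = p_gamma[ord], r_squared = r2[ord],
    log_marginal = lml[ord],
    prior_prob = exp(log_prior[ord]),
    posterior_prob = post[ord],
    pip = pip, method = method,
    n_models_evaluated = nrow(gamma), n_skipped = n_skipped,
    note = note, config = config
  ), class = "bma_result")
}

score_all_models <- function(r2_fun, gamma, n, alpha) {
  nm <- nrow(gamma)
  r2 <- numeric(nm); lml <- numeric(nm)
  for (i in seq_len(nm)) {
    idx <- which(gamma[i, ])
    k <- length(idx)
    if (k >= n - 1L) { r2[i] <- NA_real_; lml[i] <- -Inf; next }
    r2[i] <- r2_fun(idx)
    lml[i] <- zs_laplace_fast(n, k, r2[i], alpha)
  }
  list(r2 = r2, lml = lml)
}

all_gammas <- function(p) {
  stopifnot(p <= 25)
  nm <- 2L^p
  g <- matrix(FALSE, nm, p)
  for (j in seq_len(p))
    g[, j] <- rep(rep(c(FALSE, TRUE), each = 2L^(j - 1L)), length.out = nm)
  g
}

#' Exhaustive Bayesian model averaging over all predictor subsets
#'
#' Centers the outcome and every design column, evaluates the ZS-null
#' log marginal likelihood of all 2^p models, and normalizes posterior
#' model probabilities proportional to marginal likelihood times model
#' prior. Models with p_gamma >= n - 1 (unidentifiable) receive zero
#' posterior mass.
#'
#' @param x design matrix or `coded_matrix`.
#' @param y outcome vector (taken from the `coded_matrix` when omitted).
#' @param config a [bma_config()].
#' @param arm optional arm label stored in the result.
#' @return object of class `bma_result`: per-model scores sorted by
#'   posterior probability (ties: fewer variables, then lexicographic
#'   inclusion vector), per-column posterior inclusion probabilities
#'   (`pip`), and the evaluation method.
#' @export
enumerate_models <- function(x, y = NULL, config = bma_config(), arm = NULL) {
  d <- resolve_design(x, y)
  p <- ncol(d$x)
  if (p == 0L) stop("no candidate predictors", call. = FALSE)
  if (p > config$enumeration_limit)
    stop(sprintf("p = %d exceeds enumeration_limit = %d; use mcmc_bas()",
                 p, config$enumeration_limit), call. = FALSE)
  n <- nrow(d$x)
  if (n <= p + 1L)
    warning("fewer rows than predictors + 2; large models get zero mass")
  gamma <- all_gammas(p)
  colnames(gamma) <- colnames(d$x)
  sc <- score_all_models(make_r2_fun(d$x, d$y), gamma, n, config$alpha)
  n_skipped <- sum(!is.finite(sc$lml))
  finalize_bma(gamma, sc$r2, sc$lml, colnames(d$x), n, config,
               "enumeration", n_skipped, arm = arm)
}

#' Hybrid MCMC + adaptive sampling without replacement over model space
#'
#' Phase 1 runs a Metropolis-Hastings chain over inclusion vectors
#' (proposals: flip one uniformly chosen bit, occasionally swap an
#' included/excluded pair) targeting the posterior over models, caching
#' every distinct model scored and accumulating visit-frequency
#' estimates of the inclusion probabilities. Phase 2 draws further
#' *distinct* models without replacement, sampling each column
#' independently with probability equal to the current inclusion
#' estimate (clamped to [0.025, 0.975]), skipping already-scored models
#' and refreshing the estimates periodically. Final inclusion
#' probabilities and posterior model probabilities renormalize marginal
#' likelihood x prior over all unique scored models. When the budget
#' covers the whole 2^p space the entire space is scored and the result
#' equals exhaustive enumeration.
#'
#' @inheritParams enumerate_models
#' @return a `bma_result` with `method = "mcmc_bas"`.
#' @export
mcmc_bas <- function(x, y = NULL, config = bma_config(), arm = NULL) {
  d <- resolve_design(x, y)
  p <- ncol(d$x)
  if (p == 0L) stop("no candidate predictors", call. = FALSE)
  if (config$n_models < 10L) stop("sampling budget must be at least 10", call. = FALSE)
  n <- nrow(d$x)
  r2_fun <- make_r2_fun(d$x, d$y)
  set.seed(config$seed)

  if (p <= 25 && config$n_models >= 2^p) {
    gamma <- all_gammas(p)
    colnames(gamma) <- colnames(d$x)
    sc <- score_all_models(r2_fun, gamma, n, config$alpha)
    return(finalize_bma(gamma, sc$r2, sc$lml, colnames(d$x), n, config,
                        "mcmc_bas", sum(!is.finite(sc$lml)),
                        note = "budget exhausted the model space", arm = arm))
  }

  budget <- config$n_models
  cache <- new.env(hash = TRUE, parent = emptyenv())
  gamma_store <- matrix(FALSE, budget, p)
  r2_store <- numeric(budget); lml_store <- numeric(budget)
  n_scored <- 0L

  # model identity key: exact base-2 code for p <= 52 (doubles are exact
  # below 2^53), bit string otherwise
  pw2 <- 2^(seq_len(p) - 1)
  key_fun <- if (p <= 52) function(g) sprintf("%.0f", sum(pw2[g]))
             else function(g) paste(as.integer(g), collapse = "")

  score <- function(g) {
    key <- key_fun(g)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    k <- sum(g)
    if (k >= n - 1L) { r2 <- NA_real_; lml <- -Inf }
    else { r2 <- r2_fun(which(g)); lml <- zs_laplace_fast(n, k, r2, config$alpha) }
    n_scored <<- n_scored + 1L
    gamma_store[n_scored, ] <<- g
    r2_store[n_scored] <<- r2
    lml_store[n_scored] <<- lml
    rec <- list(lml = lml, prior = model_log_prior(k, p, config$model_prior))
    cache[[key]] <- rec
    rec
  }

  # phase 1: Metropolis-Hastings exploration
  iters <- config$mcmc_iterations %||% budget
  phase1_cap <- max(10L, budget %/% 2L)
  cur <- rep(FALSE, p)
  cur_sc <- score(cur)
  visits <- numeric(p); n_visits <- 0
  for (i in seq_len(iters)) {
    if (n_scored >= phase1_cap) break
    prop <- cur
    if (stats::runif(1) < 0.9 || !any(cur) || all(cur)) {
      j <- sample.int(p, 1L)
      prop[j] <- !prop[j]
    } else {
      j_in <- sample(which(cur), 1L)
      j_out <- sample(which(!cur), 1L)
      prop[j_in] <- FALSE; prop[j_out] <- TRUE
    }
    prop_sc <- score(prop)
    log_acc <- (prop_sc$lml + prop_sc$prior) - (cur_sc$lml + cur_sc$prior)
    if (is.finite(log_acc) && log(stats::runif(1)) < log_acc) {
      cur <- prop; cur_sc <- prop_sc
    }
    visits <- visits + cur; n_visits <- n_visits + 1
  }
  pip_hat <- if (n_visits > 0) visits / n_visits else rep(0.5, p)

  # phase 2: adaptive sampling without replacement. Candidates are drawn
  # in vectorized chunks; when duplicates dominate (the unscored models
  # carry little proposal mass) the sampling probabilities are
  # progressively flattened toward 1/2 so the remainder of the space
  # stays reachable, and persistent starvation ends the run early.
  eps <- 0.025
  note <- NULL
  clamp <- function(q) pmin(1 - eps, pmax(eps, q))
  pr <- clamp(pip_hat)
  misses <- 0L; refresh_at <- n_scored + 500L
  chunk <- 256L
  while (n_scored < budget) {
    u <- matrix(stats::runif(chunk * p), chunk, p, byrow = TRUE)
    cand <- sweep(u, 2L, pr, `<`)
    for (r in seq_len(chunk)) {
      if (n_scored >= budget) break
      g <- cand[r, ]
      if (is.null(cache[[key_fun(g)]])) {
        score(g)
        misses <- 0L
        if (n_scored >= refresh_at) {
          sl <- seq_len(n_scored)
          w <- lml_store[sl] +
            model_log_prior(rowSums(gamma_store[sl, , drop = FALSE]), p,
                            config$model_prior)
          w[!is.finite(w)] <- -Inf
          pw <- exp(w - max(w)); pw <- pw / sum(pw)
          pr <- clamp(drop(crossprod(gamma_store[sl, , drop = FALSE], pw)))
          refresh_at <- n_scored + 500L
        }
      } else {
        misses <- misses + 1L
        if (misses %% 2000L == 0L) pr <- (pr + 0.5) / 2  # flatten
        if (misses >= 50000L) break
      }
    }
    if (misses >= 50000L) {
      note <- "duplicate-skip starvation: stopped before exhausting budget"
      break
    }
  }

  gamma <- gamma_store[seq_len(n_scored), , drop = FALSE]
  colnames(gamma) <- colnames(d$x)
  finalize_bma(gamma, r2_store[seq_len(n_scored)], lml_store[seq_len(n_scored)],
               colnames(d$x), n, config, "mcmc_bas",
               sum(!is.finite(lml_store[seq_len(n_scored)])), note = note, arm = arm)
}

#' Ranked top-model report
#'
#' The K best models by posterior probability with the columns of the
#' conventional BMA report: Bayes factor relative to the best model
#' (best = 1), number of variables, R^2, log marginal likelihood and
#' posterior probability.
#'
#' @param result a `bma_result`.
#' @param K number of rows (default 5).
#' @return data frame with one row per model, best first.
#' @export
top_model_table <- function(result, K = 5L) {
  stopifnot(inherits(result, "bma_result"))
  if (K > result$n_models_evaluated) {
    message("K exceeds models evaluated; truncating")
    K <- result$n_models_evaluated
  }
  idx <- seq_len(K)
  data.frame(
    model = idx,
    bayes_factor = exp(result$log_marginal[idx] - result$log_marginal[1L]),
    n_variables = result$p_gamma[idx],
    r_squared = result$r_squared[idx],
    log_marginal = result$log_marginal[idx],
    posterior_prob = result$posterior_prob[idx]
  )
}

#' @export
print.bma_result <- function(x, ...) {
  cat(sprintf("BMA over %d columns (%s%s): %d models scored, n = %d\n",
              length(x$columns), x$method,
              if (!is.null(x$arm)) paste0(", arm ", x$arm) else "",
              x$n_models_evaluated, x$n))
  cat("Top model posterior prob:", signif(x$posterior_prob[1L], 3),
      "with", x$p_gamma[1L], "variables\n")
  top_pip <- sort(x$pip, decreasing = TRUE)
  show <- utils::head(top_pip, 8L)
  cat("Leading inclusion probabilities:\n")
  for (nm in names(show)) cat(sprintf("  %-32s %.3f\n", nm, show[[nm]]))
  invisible(x)
}
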