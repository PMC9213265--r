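# Inferential machinery: Dunnett and Steel many-to-one comparisons with
# familywise adjustment over correlated contrasts, maximum-likelihood
# proportional-odds (cumulative-logit) regression, and the two-step
# variable-selection filter.

# P(|T_j| <= c for all j) under the central multivariate t (df) or normal
# (df = Inf) with correlation matrix R. Deterministic: TVPACK (dim <= 3, via
# inclusion-exclusion over orthant CDFs) for the t, Miwa for the normal.
mvt_rect <- function(c_, R, df = Inf) {
  k <- nrow(R)
  if (!is.finite(c_)) return(1)
  if (k == 1) {
    return(if (is.finite(df)) stats::pt(c_, df) - stats::pt(-c_, df)
           else stats::pnorm(c_) - stats::pnorm(-c_))
  }
  if (is.finite(df)) {
    df <- as.integer(round(df))
    cdf <- function(u) mvtnorm::pmvt(upper = u, df = df, corr = R,
                                     algorithm = mvtnorm::TVPACK())
    if (k == 2) {
      p <- cdf(c(c_, c_)) - cdf(c(-c_, c_)) - cdf(c(c_, -c_)) +
        cdf(c(-c_, -c_))
    } else {
      # 3-dim inclusion-exclusion
      signs <- expand.grid(s1 = c(1, -1), s2 = c(1, -1), s3 = c(1, -1))
      p <- sum(apply(signs, 1, function(s)
        prod(s) * cdf(c_ * as.numeric(s))))
    }
    return(min(max(p, 0), 1))
  }
  p <- mvtnorm::pmvnorm(lower = rep(-c_, k), upper = rep(c_, k), corr = R,
                        algorithm = mvtnorm::Miwa(steps = 512))
  min(max(as.numeric(p), 0), 1)
}

many_one_setup <- function(values, groups, control) {
  groups <- as.factor(groups)
  if (!control %in% levels(groups))
    stop("control level '", control, "' not present", call. = FALSE)
  lev <- levels(droplevels(groups))
  cases <- setdiff(lev, control)
  if (!length(cases)) stop("no case group present", call. = FALSE)
  list(groups = groups, cases = cases,
       split = split(values, factor(groups, levels = c(control, cases))))
}

# correlation of many-to-one contrasts sharing one control
many_one_corr <- function(n0, n_case) {
  lam <- sqrt(n_case / (n_case + n0))
  R <- outer(lam, lam)
  diag(R) <- 1
  R
}

#' Dunnett many-to-one test
#'
#' Compares each case group with the single control using pooled-variance
#' t statistics and adjusts two-sided p-values for the family of correlated
#' contrasts via the multivariate t distribution with the
#' sample-size-determined correlation. With a single case group this reduces
#' to the pooled two-sample t test.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor of the same length; one level is the control.
#' @param control Name of the control level (default `"control"`).
#' @return Tibble with one row per case group: `comparison`, `estimate`
#'   (case mean minus control mean), `statistic`, `df`, `p_unadjusted`,
#'   `p_adjusted`.
#' @export
dunnett_test <- function(values, groups, control = "control") {
  s <- many_one_setup(values, groups, control)
  ns <- lengths(s$split)
  if (any(ns < 2))
    stop("each group needs at least 2 observations", call. = FALSE)
  k <- length(s$cases)
  means <- vapply(s$split, mean, numeric(1))
  vars <- vapply(s$split, stats::var, numeric(1))
  N <- sum(ns)
  df <- N - (k + 1)
  s2 <- sum((ns - 1) * vars) / df
  est <- means[-1] - means[1]
  if (s2 <= 0) {
    warning("zero pooled variance; p-values set to 1")
    return(tibble::tibble(comparison = s$cases, estimate = est,
                          statistic = 0, df = df, p_unadjusted = 1,
                          p_adjusted = 1))
  }
  tstat <- est / sqrt(s2 * (1 / ns[-1] + 1 / ns[1]))
  R <- many_one_corr(ns[1], ns[-1])
  p_un <- 2 * stats::pt(-abs(tstat), df)
  p_ad <- vapply(abs(tstat), function(ti) 1 - mvt_rect(ti, R, df), numeric(1))
  tibble::tibble(comparison = s$cases, estimate = unname(est),
                 statistic = unname(tstat), df = df,
                 p_unadjusted = unname(p_un),
                 p_adjusted = pmax(unname(p_ad), unname(p_un)))
}

# midrank Z statistic of one case group vs control, tie-corrected variance
steel_z <- function(x0, x1) {
  n0 <- length(x0); n1 <- length(x1); N <- n0 + n1
  r <- rank(c(x0, x1))
  W <- sum(r[(n0 + 1):N])
  E <- n1 * (N + 1) / 2
  ties <- table(c(x0, x1))
  V <- n0 * n1 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (V <= 0) return(list(z = 0, degenerate = TRUE, W = W))
  list(z = (W - E) / sqrt(V), degenerate = FALSE, W = W)
}

#' Steel many-to-one rank test
#'
#' For each case group, a Wilcoxon rank-sum comparison against the control
#' with midranks for ties and a tie-corrected variance; the two-sided
#' p-values are adjusted jointly over the correlated contrasts with the
#' multivariate normal approximation (or by permutation of the group
#' labels). Suitable for binary 0/1 indicators, where it compares
#' proportions. With a single case group it reduces to the tie-corrected
#' normal-approximation Wilcoxon test.
#'
#' @inheritParams dunnett_test
#' @param method `"normal"` (default) for the multivariate-normal
#'   adjustment, `"permutation"` for a joint max-|Z| permutation null.
#' @param n_perm Number of permutations when `method = "permutation"`.
#' @return Tibble: `comparison`, `statistic` (standardized rank sum),
#'   `p_unadjusted`, `p_adjusted`.
#' @export
steel_test <- function(values, groups, control = "control",
                       method = c("normal", "permutation"),
                       n_perm = 10000) {
  method <- match.arg(method)
  s <- many_one_setup(values, groups, control)
  ns <- lengths(s$split)
  if (any(ns < 2))
    stop("each group needs at least 2 observations", call. = FALSE)
  x0 <- s$split[[1]]
  zs <- lapply(s$split[-1], function(xi) steel_z(x0, xi))
  z <- vapply(zs, `[[`, numeric(1), "z")
  if (all(vapply(zs, `[[`, logical(1), "degenerate"))) {
    warning("constant pooled sample; p-values set to 1")
    return(tibble::tibble(comparison = s$cases, statistic = z,
                          p_unadjusted = 1, p_adjusted = 1))
  }
  p_un <- 2 * stats::pnorm(-abs(z))
  if (method == "normal") {
    R <- many_one_corr(ns[1], ns[-1])
    p_ad <- vapply(abs(z), function(zi) 1 - mvt_rect(zi, R, Inf), numeric(1))
  } else {
    p_ad <- steel_perm_p(values, s$groups, control = names(s$split)[1],
                         cases = s$cases, z_obs = abs(z), n_perm = n_perm)
  }
  tibble::tibble(comparison = s$cases, statistic = unname(z),
                 p_unadjusted = unname(p_un),
                 p_adjusted = pmax(unname(p_ad), unname(p_un)))
}

# permutation null of max |Z| over the contrasts; p_i = P(max|Z*| >= |z_i|)
steel_perm_p <- function(values, groups, control, cases, z_obs, n_perm) {
  g <- as.character(groups)
  idx0 <- which(g == control)
  idx_case <- lapply(cases, function(cs) which(g == cs))
  n_all <- length(values)
  maxz <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n_all)
    x0 <- values[perm[idx0]]
    zb <- vapply(idx_case, function(ii) abs(steel_z(x0, values[perm[ii]])$z),
                 numeric(1))
    maxz[b] <- max(zb)
  }
  vapply(z_obs, function(zi) (1 + sum(maxz >= zi - 1e-12)) / (n_perm + 1),
         numeric(1))
}

## ---- proportional-odds (cumulative-logit) regression ----------------------

po_loglik <- function(theta, x, y, K) {
  alpha <- theta[seq_len(K - 1)]
  beta <- theta[-seq_len(K - 1)]
  eta <- if (length(beta)) drop(x %*% beta) else rep(0, length(y))
  G <- stats::plogis(outer(eta, alpha, "+"))   # n x (K-1), gamma_k = P(Y>=k)
  g_lo <- cbind(1, G)[cbind(seq_along(y), y + 1L)]        # gamma_y
  g_hi <- cbind(G, 0)[cbind(seq_along(y), y + 1L)]        # gamma_{y+1}
  d <- g_lo - g_hi
  if (any(d <= 0)) return(-Inf)
  sum(log(d))
}

po_grad <- function(theta, x, y, K) {
  n <- length(y)
  alpha <- theta[seq_len(K - 1)]
  beta <- theta[-seq_len(K - 1)]
  eta <- if (length(beta)) drop(x %*% beta) else rep(0, n)
  G <- stats::plogis(outer(eta, alpha, "+"))
  g_lo <- cbind(1, G)[cbind(seq_len(n), y + 1L)]
  g_hi <- cbind(G, 0)[cbind(seq_len(n), y + 1L)]
  d <- g_lo - g_hi
  w_lo <- ifelse(y >= 1L, g_lo * (1 - g_lo), 0) / d   # d logit term, alpha_y
  w_hi <- ifelse(y <= K - 2L, g_hi * (1 - g_hi), 0) / d  # alpha_{y+1}
  ga <- vapply(seq_len(K - 1), function(k)
    sum(w_lo[y == k]) - sum(w_hi[y == k - 1L]), numeric(1))
  gb <- if (length(beta)) drop(crossprod(x, w_lo - w_hi)) else numeric(0)
  c(ga, gb)
}

# observed information via central differences of the analytic gradient
po_hessian <- function(theta, x, y, K) {
  p <- length(theta)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    h <- 1e-5 * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    H[, j] <- (po_grad(tp, x, y, K) - po_grad(tm, x, y, K)) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Fit a proportional-odds (cumulative-logit) model
#'
#' Maximizes the likelihood of `P(Y >= k | x) = logistic(alpha_k + x'beta)`
#' for an ordered outcome with categories `0 < 1 < ... < K-1` by Newton
#' iteration with step-halving (the log-likelihood is non-decreasing across
#' iterations). A single `beta` per covariate acts across all cutpoints, so
#' positive coefficients mean higher odds of the upper categories. Standard
#' errors come from the observed information; confidence intervals are Wald
#' intervals exponentiated to the odds-ratio scale.
#'
#' @param x Covariate matrix or data frame (numeric/logical columns);
#'   `NULL` or zero columns fits the intercepts-only model, whose maximum is
#'   the closed-form empirical cumulative logits.
#' @param y Ordered outcome: integer vector in `0:(K-1)`, or a factor whose
#'   level order is the outcome order. All levels must be observed and at
#'   least three are required.
#' @param conf_level Confidence level for the odds-ratio intervals.
#' @param tol Target tolerance on the max-norm of the score; iteration also
#'   stops once the log-likelihood ceases to improve at floating-point
#'   scale, and the fit is flagged non-converged only when the final score
#'   max-norm exceeds `max(tol, 1e-7 * n)` (a per-observation criterion).
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `ordinal_fit`: a list with `intercepts`
#'   (named, strictly decreasing), `coefficients` (tibble with `term`,
#'   `estimate`, `std_error`, `or`, `ci_low`, `ci_high`, `p_value`),
#'   `vcov`, `logLik`, `n`, `iterations`, `gradient_norm`, `converged`.
#' @export
fit_proportional_odds <- function(x, y, conf_level = 0.95, tol = 1e-8,
                                  max_iter = 100L) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  K <- length(unique(y))
  if (K < 3) stop("outcome must have at least 3 observed levels",
                  call. = FALSE)
  if (!all(sort(unique(y)) == 0:(K - 1)))
    stop("outcome levels must be consecutive integers starting at 0",
         call. = FALSE)
  if (is.null(x)) {
    x <- matrix(numeric(0), nrow = length(y), ncol = 0)
  } else {
    if (is.data.frame(x)) x <- as.matrix(as.data.frame(lapply(x, as.numeric)))
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    if (nrow(x) != length(y)) stop("nrow(x) != length(y)", call. = FALSE)
    cv <- apply(x, 2, stats::var)
    if (any(cv == 0))
      stop("constant covariate: ",
           paste(colnames(x)[cv == 0], collapse = ", "), call. = FALSE)
  }
  p <- ncol(x)
  if (p > 0 && is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))

  # standardize covariates internally so the Newton iteration is well
  # conditioned regardless of covariate units; estimates, standard errors
  # and the information matrix are mapped back to the original scale below
  if (p > 0) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    xw <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  } else {
    ctr <- scl <- numeric(0)
    xw <- x
  }

  # start at the empirical cumulative logits, beta = 0
  marg <- rev(cumsum(rev(tabulate(y + 1L, K) / length(y))))[-1]
  theta <- c(stats::qlogis(marg), rep(0, p))
  ll <- po_loglik(theta, xw, y, K)
  iter <- 0L
  trace <- numeric(0)
  repeat {
    g <- po_grad(theta, xw, y, K)
    if (max(abs(g)) < tol || iter >= max_iter) break
    iter <- iter + 1L
    H <- po_hessian(theta, xw, y, K)
    step <- tryCatch(-solve(H, g), error = function(e) g)  # fallback: ascent
    lam <- 1
    repeat {
      cand <- theta + lam * step
      ll_new <- po_loglik(cand, xw, y, K)
      ok_alpha <- all(diff(cand[seq_len(K - 1)]) < 0)
      if (is.finite(ll_new) && ll_new >= ll && ok_alpha) break
      lam <- lam / 2
      if (lam < 1e-12) {
        stop("proportional-odds fit failed to improve (possible ",
             "separation); log-likelihood trace: ",
             paste(signif(c(trace, ll), 8), collapse = " -> "),
             call. = FALSE)
      }
    }
    theta <- theta + lam * step
    # stop once the likelihood stops improving at floating-point scale;
    # the score can stall just above `tol` because the Newton direction
    # uses a finite-difference information matrix
    stalled <- ll_new - ll < 1e-11 * (1 + abs(ll_new))
    ll <- ll_new
    trace <- c(trace, ll)
    if (stalled) break
  }
  g <- po_grad(theta, xw, y, K)
  # convergence flagged on the per-observation score: near-separated fits
  # have a likelihood that is flat at floating-point scale while the raw
  # score norm still reflects the sample size
  converged <- max(abs(g)) < max(tol, 1e-7 * length(y))

  if (!converged)
    warning("proportional-odds fit did not converge after ", iter,
            " iterations (|score| = ", signif(max(abs(g)), 3), ")")

  H <- po_hessian(theta, xw, y, K)
  vcw <- tryCatch(solve(-H), error = function(e)
    matrix(NA_real_, length(theta), length(theta)))
  # map (intercepts, standardized slopes) back to the original covariate
  # scale: beta_j = b_j / s_j, alpha_k = a_k - sum_j b_j m_j / s_j
  A <- diag(length(theta))
  if (p > 0) {
    for (j in seq_len(p)) {
      A[seq_len(K - 1), K - 1 + j] <- -ctr[j] / scl[j]
      A[K - 1 + j, K - 1 + j] <- 1 / scl[j]
    }
    theta <- drop(A %*% theta)
  }
  vc <- A %*% vcw %*% t(A)
  se <- sqrt(pmax(diag(vc), 0))
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
  alpha <- theta[seq_len(K - 1)]
  names(alpha) <- paste0("alpha_", seq_len(K - 1))
  coefs <- if (p > 0) {
    b <- theta[-seq_len(K - 1)]
    sb <- se[-seq_len(K - 1)]
    tibble::tibble(term = colnames(x), estimate = b, std_error = sb,
                   or = exp(b), ci_low = exp(b - zcrit * sb),
                   ci_high = exp(b + zcrit * sb),
                   p_value = 2 * stats::pnorm(-abs(b / sb)))
  } else {
    tibble::tibble(term = character(), estimate = numeric(),
                   std_error = numeric(), or = numeric(),
                   ci_low = numeric(), ci_high = numeric(),
                   p_value = numeric())
  }
  structure(list(intercepts = alpha,
                 intercept_se = se[seq_len(K - 1)],
                 coefficients = coefs, vcov = vc, logLik = ll,
                 n = length(y), iterations = iter,
                 gradient_norm = max(abs(g)), converged = converged),
            class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat("Proportional-odds (cumulative-logit) fit\n")
  cat(sprintf("  n = %d, logLik = %.3f, iterations = %d%s\n", x$n, x$logLik,
              x$iterations, if (x$converged) "" else " (NOT converged)"))
  cat("  intercepts:", paste(sprintf("%s = %.4f", names(x$intercepts),
                                     x$intercepts), collapse = ", "), "\n")
  if (nrow(x$coefficients)) {
    cat("  coefficients:\n")
    print(as.data.frame(x$coefficients), digits = 4, row.names = FALSE)
  }
  invisible(x)
}

## ---- two-step variable selection ------------------------------------------

#' Variable-selection configuration
#'
#' @param alpha Significance threshold for step 1 (default 0.05).
#' @param min_incidence Minimum incidence (proportion) a categorical
#'   variable must reach in the control or either case group (default 0.05).
#' @param categorical_rule How step 1 combines significance and incidence
#'   for categorical variables: `"and"` (significant in both comparisons AND
#'   incidence above the floor — the default reading) or `"or"` (either
#'   condition suffices).
#' @param force_include,force_exclude Named character vectors
#'   (`variable = reason`) or bare character vectors applied in step 2.
#' @param collinear_pairs List of `c(drop = ..., keep = ...)` pairs: when
#'   both survive step 1 (or the kept one does), the `drop` variable is
#'   removed as collinear.
#' @return A `selection_config` list.
#' @export
selection_config <- function(alpha = 0.05, min_incidence = 0.05,
                             categorical_rule = c("and", "or"),
                             force_include = character(),
                             force_exclude = character(),
                             collinear_pairs = list()) {
  stopifnot(alpha > 0, alpha < 1, min_incidence >= 0, min_incidence <= 1)
  structure(list(alpha = alpha, min_incidence = min_incidence,
                 categorical_rule = match.arg(categorical_rule),
                 force_include = force_include,
                 force_exclude = force_exclude,
                 collinear_pairs = collinear_pairs),
            class = "selection_config")
}

with_reasons <- function(x) {
  if (is.null(names(x))) stats::setNames(rep("", length(x)), x) else x
}

#' Two-step explanatory-variable selection
#'
#' Step 1 keeps continuous variables significant (below `alpha`) in both
#' case-vs-control comparisons, and categorical variables that are both
#' significant in both comparisons and reach the incidence floor in the
#' control or either case group (rule configurable). Step 2 applies the
#' forced inclusions/exclusions and removes the `drop` member of each
#' declared collinear pair. Every decision is written to an audit log with
#' its reason.
#'
#' @param desc Output of [descriptive_table()].
#' @param config A [selection_config()].
#' @return List: `selected` (character vector in table order), `audit`
#'   (tibble `variable`, `stage`, `action`, `reason`).
#' @export
select_variables <- function(desc, config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  audit <- list()
  note <- function(v, stage, action, reason)
    audit[[length(audit) + 1]] <<- tibble::tibble(
      variable = v, stage = stage, action = action, reason = reason)

  selected <- character()
  for (i in seq_len(nrow(desc))) {
    v <- desc$variable[i]
    sig <- !is.na(desc$p_case_I[i]) && !is.na(desc$p_case_II[i]) &&
      desc$p_case_I[i] < config$alpha && desc$p_case_II[i] < config$alpha
    if (desc$type[i] == "categorical") {
      inc <- max(desc$stat_control[i], desc$stat_case_I[i],
                 desc$stat_case_II[i]) / 100
      inc_ok <- inc >= config$min_incidence
      keep <- if (config$categorical_rule == "and") sig && inc_ok
              else sig || inc_ok
      reason <- sprintf("step1: significant in both = %s, incidence %.1f%% %s %.0f%%",
                        sig, inc * 100, if (inc_ok) ">=" else "<",
                        config$min_incidence * 100)
    } else {
      keep <- sig
      reason <- sprintf("step1: significant in both comparisons = %s", sig)
    }
    note(v, "step1", if (keep) "selected" else "dropped", reason)
    if (keep) selected <- c(selected, v)
  }

  fx <- with_reasons(config$force_exclude)
  for (v in names(fx)) {
    if (v %in% selected) {
      selected <- setdiff(selected, v)
      note(v, "step2", "dropped",
           paste0("forced exclusion",
                  if (nzchar(fx[[v]])) paste0(": ", fx[[v]]) else ""))
    }
  }
  for (pair in config$collinear_pairs) {
    drop <- pair[["drop"]]; keep <- pair[["keep"]]
    if (drop %in% selected && keep %in% selected) {
      selected <- setdiff(selected, drop)
      note(drop, "step2", "dropped",
           paste0("collinear with ", keep))
    }
  }
  fi <- with_reasons(config$force_include)
  for (v in names(fi)) {
    if (!v %in% selected) {
      selected <- c(selected, v)
      note(v, "step2", "selected",
           paste0("forced: ",
                  if (nzchar(fi[[v]])) fi[[v]] else "clinical perspective"))
    }
  }
  ord <- desc$variable[desc$variable %in% selected]
  ord <- c(ord, setdiff(selected, ord))
  list(selected = ord, audit = dplyr::bind_rows(audit))
}
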