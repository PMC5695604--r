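## Huggins robust design: closed secondary occasions nested in open
## primary periods with survival and Markovian temporary emigration.

#' Fit a Huggins robust-design model
#'
#' Combines within-primary Huggins conditional components with a hidden
#' two-state (present / temporarily absent) Markov chain between
#' primaries: survival `S` (optionally sex-specific), emigration
#' `gamma'' = P(absent_t | present_{t-1})` and
#' `gamma' = P(absent_t | absent_{t-1})`.  The likelihood conditions on
#' each individual's first-capture primary: the first primary
#' contributes the closed conditional component (history probability
#' over `p*`), subsequent primaries are evaluated by forward recursion
#' over availability states (present, absent, dead) with the secondary
#' history as emission.  With a single primary period the likelihood
#' reduces exactly to [fit_huggins()].  Within-year abundances are
#' Horvitz-Thompson sums over that year's detected individuals.
#'
#' @param ch_list List of `capture_history` objects, one per primary
#'   period (rownames of `det` identify individuals across years).
#' @param model List of logicals: `s_sex` (sex-specific survival),
#'   `p_year` (year-varying p and c intercepts), `p_sex` (sex effect on
#'   p and c equally), `behavior` (p != c, default TRUE).
#' @param n_restarts Random restarts for the optimizer.
#' @return A `robust_fit`: coefficients, vcov, logL, K, AICc, `S`
#'   (per-sex if requested), `gamma1`, `gamma2`, and `Nhat` (data frame
#'   per year with SE and log-normal CI).
#' @export
fit_robust_design <- function(ch_list,
                              model = list(s_sex = FALSE, p_year = FALSE,
                                           p_sex = FALSE, behavior = TRUE),
                              n_restarts = 3) {
  if (length(ch_list) < 2)
    stop("single primary period: use fit_huggins()")
  model <- utils::modifyList(list(s_sex = FALSE, p_year = FALSE,
                                  p_sex = FALSE, behavior = TRUE), model)
  n_prim <- length(ch_list)
  Tt <- vapply(ch_list, function(x) ncol(x$det), integer(1))

  ids <- sort(unique(unlist(lapply(ch_list, function(x) rownames(x$det)))))
  n <- length(ids)
  ## per-individual, per-primary summaries: first secondary detection
  ## occasion, number of detections; sex covariate
  F_ <- matrix(NA_integer_, n, n_prim)
  ND <- matrix(0L, n, n_prim)
  sex <- rep(0.5, n)
  for (t in seq_len(n_prim)) {
    d <- ch_list[[t]]$det
    m <- match(rownames(d), ids)
    F_[m, t] <- apply(d, 1, function(r) which(r == 1)[1])
    ND[m, t] <- rowSums(d)
    sex[m] <- ch_list[[t]]$sex
  }
  fprim <- apply(ND > 0, 1, function(r) which(r)[1])

  par_names <- c("s_intercept",
                 if (model$s_sex) "s_sex",
                 "gamma2", "gamma1",
                 if (model$p_year) paste0("p_y", seq_len(n_prim)) else "p",
                 if (model$behavior) {
                   if (model$p_year) paste0("c_y", seq_len(n_prim)) else "c"
                 },
                 if (model$p_sex) "p_sex")
  K <- length(par_names)
  ix <- function(nm) which(par_names == nm)

  detection_probs <- function(beta) {
    b_sex <- if (model$p_sex) beta[ix("p_sex")] else 0
    p <- c_ <- matrix(0, n, n_prim)
    for (t in seq_len(n_prim)) {
      p0 <- if (model$p_year) beta[ix(paste0("p_y", t))] else beta[ix("p")]
      c0 <- if (!model$behavior) p0 else
        if (model$p_year) beta[ix(paste0("c_y", t))] else beta[ix("c")]
      p[, t] <- plogis_(p0 + b_sex * sex)
      c_[, t] <- plogis_(c0 + b_sex * sex)
    }
    list(p = pmin(pmax(p, 1e-12), 1 - 1e-12),
         c = pmin(pmax(c_, 1e-12), 1 - 1e-12))
  }

  nll <- function(beta) {
    pc <- detection_probs(beta)
    S <- plogis_(beta[ix("s_intercept")] +
                 (if (model$s_sex) beta[ix("s_sex")] * sex else 0))
    g2 <- plogis_(beta[ix("gamma2")])   # present -> absent
    g1 <- plogis_(beta[ix("gamma1")])   # absent stays absent
    ## log emission given present, per individual x primary
    lg <- matrix(0, n, n_prim)
    for (t in seq_len(n_prim)) {
      p <- pc$p[, t]; cc <- pc$c[, t]
      zero <- ND[, t] == 0L
      lg[, t] <- ifelse(zero, Tt[t] * log(1 - p),
                        (F_[, t] - 1) * log(1 - p) + log(p) +
                        (ND[, t] - 1) * log(cc) +
                        (Tt[t] - F_[, t] - (ND[, t] - 1)) * log(1 - cc))
    }
    lpstar <- log1p(-(1 - pc$p)^rep(Tt, each = n))
    a_pres <- a_abs <- a_dead <- rep(0, n)
    for (t in seq_len(n_prim)) {
      started <- fprim < t
      if (any(started)) {
        np <- (a_pres * (1 - g2) + a_abs * (1 - g1)) * S
        na_ <- (a_pres * g2 + a_abs * g1) * S
        nd_ <- a_dead + (a_pres + a_abs) * (1 - S)
        zero <- ND[, t] == 0L
        a_pres <- ifelse(started, np * exp(lg[, t]), a_pres)
        a_abs <- ifelse(started, na_ * zero, a_abs)
        a_dead <- ifelse(started, nd_ * zero, a_dead)
      }
      enter <- fprim == t
      a_pres[enter] <- exp(lg[enter, t] - lpstar[enter, t])
    }
    tot <- a_pres + a_abs + a_dead
    -sum(log(pmax(tot, 1e-300)))
  }

  opt <- optimize_nll(nll, K, n_restarts)
  beta <- setNames(opt$par, par_names)
  vcov <- tryCatch(solve(opt$hessian), error = function(e)
    matrix(NA_real_, K, K))
  dimnames(vcov) <- list(par_names, par_names)

  pc <- detection_probs(beta)
  pstar <- 1 - (1 - pc$p)^rep(Tt, each = n)
  boundary <- any(pc$p > 1 - 1e-6) || any(abs(beta) > 15)

  ## per-year Horvitz-Thompson abundance
  nhat <- do.call(rbind, lapply(seq_len(n_prim), function(t) {
    obs <- ND[, t] > 0L
    Nh <- sum(1 / pstar[obs, t])
    var_ht <- sum((1 - pstar[obs, t]) / pstar[obs, t]^2)
    grad <- vapply(seq_len(K), function(k) {
      h <- 1e-5; b2 <- beta; b2[k] <- b2[k] + h
      p2 <- detection_probs(b2)$p[, t]
      ps2 <- 1 - (1 - p2)^Tt[t]
      (sum(1 / ps2[obs]) - Nh) / h
    }, numeric(1))
    vb <- if (anyNA(vcov)) 0 else max(0, t(grad) %*% vcov %*% grad)
    vN <- var_ht + vb
    nobs <- sum(obs)
    ci <- if (Nh - nobs > 1e-8) {
      cf <- exp(1.96 * sqrt(log(1 + vN / (Nh - nobs)^2)))
      c(nobs + (Nh - nobs) / cf, nobs + (Nh - nobs) * cf)
    } else c(nobs, nobs + 1.96 * sqrt(vN))
    data.frame(year = ch_list[[t]]$year, n = nobs, Nhat = Nh,
               se = sqrt(vN), ci_lower = ci[1], ci_upper = ci[2])
  }))
  rownames(nhat) <- NULL

  S_hat <- plogis_(beta[ix("s_intercept")] +
                   (if (model$s_sex) c(F = 0, M = beta[ix("s_sex")]) else 0))
  if (model$s_sex) names(S_hat) <- c("F", "M")
  n_eff <- sum(vapply(ch_list, function(x) nrow(x$det) * ncol(x$det),
                      numeric(1)))
  logL <- -opt$value
  structure(list(
    model = paste0("S(", if (model$s_sex) "sex" else ".", ")G2(.)G1(.)",
                   "p(", if (model$p_year) "y" else ".",
                   if (model$p_sex) "+sex" else "", ")",
                   if (model$behavior) "c(...)" else ""),
    beta = beta, vcov = vcov, logL = logL, K = K,
    AICc = aicc_of(logL, K, n_eff), n_eff = n_eff,
    S = S_hat,
    gamma2 = unname(plogis_(beta[ix("gamma2")])),
    gamma1 = unname(plogis_(beta[ix("gamma1")])),
    Nhat = nhat, param_names = par_names, boundary = boundary,
    converged = opt$convergence == 0),
    class = c("robust_fit", "model_fit"))
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf("Huggins robust design %s: logL = %.2f, K = %d, AICc = %.2f\n",
              x$model, x$logL, x$K, x$AICc))
  cat(sprintf("  S = %s, gamma'' = %.3f, gamma' = %.3f\n",
              paste(sprintf("%.3f", x$S), collapse = "/"),
              x$gamma2, x$gamma1))
  print(x$Nhat, digits = 4)
  invisible(x)
}
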