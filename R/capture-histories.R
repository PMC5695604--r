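## Capture histories and individual covariates for closed-capture and
## robust-design models.

#' Build capture histories with spatial and sex covariates
#'
#' Collapses detections to one binary vector per individual per year
#' (multiple samples in the same occasion count once) and computes the
#' trap-density covariate `dbar`: for each detection, the Euclidean
#' distance from the detection snare to the next-nearest snare deployed
#' that year, averaged over all of the individual's detection events in
#' the year.  Individuals with no detection in a year are excluded from
#' that year's history (conditional-likelihood data).
#'
#' @param detections Data frame with columns individual, year, occasion,
#'   snare_id (one row per detection event; duplicates allowed).
#' @param snares Data frame with snare_id, x_km, y_km (all assumed
#'   deployed every year unless a `year` column restricts them).
#' @param occasions Occasions per year (integer or named vector by
#'   year).
#' @param sex Optional named character vector (individual -> "F"/"M"/
#'   "unknown") attached as a covariate.
#' @return List of `capture_history` objects, one per year: `det`
#'   (individuals x occasions 0/1 matrix, rownames = individual ids),
#'   `sex` (0 = F, 1 = M, 0.5 = unknown), `dbar` (km), `year`.
#' @export
build_capture_histories <- function(detections, snares, occasions,
                                    sex = NULL) {
  bad <- setdiff(unique(detections$snare_id), snares$snare_id)
  if (length(bad))
    stop("detection at unknown snare(s): ", paste(bad, collapse = ", "))
  years <- sort(unique(detections$year))
  occ_by_year <- if (length(occasions) == 1)
    setNames(rep(occasions, length(years)), years) else occasions

  out <- lapply(years, function(t) {
    d <- detections[detections$year == t, ]
    sn <- if ("year" %in% names(snares))
      snares[snares$year == t, ] else snares
    ## next-nearest-snare distance for every snare deployed this year
    dm <- as.matrix(dist(sn[, c("x_km", "y_km")]))
    diag(dm) <- Inf
    nn <- apply(dm, 1, min)
    names(nn) <- sn$snare_id

    ids <- sort(unique(d$individual))
    T <- as.integer(occ_by_year[as.character(t)])
    det <- matrix(0L, length(ids), T, dimnames = list(ids, NULL))
    ev <- unique(d[, c("individual", "occasion", "snare_id")])
    det[cbind(match(ev$individual, ids), ev$occasion)] <- 1L
    dbar <- vapply(ids, function(id)
      mean(nn[ev$snare_id[ev$individual == id]]), numeric(1))
    sx <- rep(0.5, length(ids))
    if (!is.null(sex)) {
      s <- sex[ids]
      sx <- ifelse(is.na(s) | s == "unknown", 0.5,
                   ifelse(s == "M", 1, 0))
    }
    structure(list(det = det, sex = sx, dbar = dbar, year = t),
              class = "capture_history")
  })
  names(out) <- years
  out
}

#' @export
print.capture_history <- function(x, ...) {
  cat(sprintf("capture history %s: %d individuals x %d occasions (%d detections)\n",
              x$year, nrow(x$det), ncol(x$det), sum(x$det)))
  invisible(x)
}

#' Simulate closed-population capture histories
#'
#' Direct model-based simulator for the Huggins closed-capture model:
#' per occasion, uncaptured-so-far individuals are detected with
#' probability `p`, previously captured ones with probability `c`
#' (behavioral response).  Only individuals detected at least once are
#' returned.
#'
#' @param N True abundance.
#' @param T Occasions.
#' @param p First-capture probability (scalar or length-N vector).
#' @param c_resp Recapture probability (default `p`).
#' @param sex Optional 0/1 covariate vector of length N (returned for
#'   detected individuals).
#' @param seed Optional integer seed.
#' @return A `capture_history` (det, sex, dbar = 0, year = 1).
#' @export
simulate_huggins_histories <- function(N, T, p, c_resp = p, sex = NULL,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- rep_len(p, N); c_resp <- rep_len(c_resp, N)
  det <- matrix(0L, N, T)
  seen <- rep(FALSE, N)
  for (j in seq_len(T)) {
    pr <- ifelse(seen, c_resp, p)
    hit <- runif(N) < pr
    det[hit, j] <- 1L
    seen <- seen | hit
  }
  keep <- rowSums(det) > 0
  det <- det[keep, , drop = FALSE]
  rownames(det) <- sprintf("ind%04d", which(keep))
  structure(list(det = det,
                 sex = if (is.null(sex)) rep(0.5, nrow(det)) else sex[keep],
                 dbar = rep(0, nrow(det)), year = 1),
            class = "capture_history")
}

#' Simulate robust-design capture histories
#'
#' Individuals survive between primary periods with probability `S`,
#' temporarily emigrate (Markovian: present -> absent with `gamma2`
#' = gamma'', absent stays absent with `gamma1` = gamma'), and are
#' detected within primaries under the Huggins p/c scheme.  Recruits
#' can be added per primary to realize a trajectory.
#'
#' @param N1 Abundance in primary 1 (alive and in the study area).
#' @param n_primary,n_secondary Design dimensions.
#' @param S Annual survival.
#' @param gamma2 P(absent at t | present at t-1) (gamma'').
#' @param gamma1 P(absent at t | absent at t-1) (gamma').
#' @param p,c_resp Within-primary detection probabilities.
#' @param recruits Integer vector (length `n_primary`, first entry
#'   ignored) of new individuals entering before each primary.
#' @param seed Optional integer seed.
#' @return List of `capture_history` objects (one per primary; only
#'   individuals with >= 1 detection in that primary appear), plus
#'   attribute `truth` with per-primary numbers present.
#' @export
simulate_robust_histories <- function(N1, n_primary, n_secondary, S,
                                      gamma2, gamma1, p, c_resp = p,
                                      recruits = rep(0L, n_primary),
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state <- rep(1L, N1)    # 1 present, 2 absent, 3 dead
  ids <- sprintf("ind%04d", seq_len(N1))
  n_tot <- N1
  out <- vector("list", n_primary)
  n_present <- integer(n_primary)
  for (t in seq_len(n_primary)) {
    if (t > 1) {
      surv <- runif(length(state)) < S
      state[!surv & state != 3L] <- 3L
      pres <- state == 1L; abs_ <- state == 2L
      go <- pres & runif(length(state)) < gamma2
      stay_out <- abs_ & runif(length(state)) < gamma1
      state[abs_ & !stay_out] <- 1L
      state[go] <- 2L
      if (recruits[t] > 0) {
        ids <- c(ids, sprintf("ind%04d", n_tot + seq_len(recruits[t])))
        state <- c(state, rep(1L, recruits[t]))
        n_tot <- n_tot + recruits[t]
      }
    }
    pres_i <- which(state == 1L)
    n_present[t] <- length(pres_i)
    det <- matrix(0L, length(pres_i), n_secondary)
    seen <- rep(FALSE, length(pres_i))
    for (j in seq_len(n_secondary)) {
      pr <- ifelse(seen, c_resp, p)
      hit <- runif(length(pres_i)) < pr
      det[hit, j] <- 1L
      seen <- seen | hit
    }
    keep <- rowSums(det) > 0
    det <- det[keep, , drop = FALSE]
    rownames(det) <- ids[pres_i][keep]
    out[[t]] <- structure(list(det = det, sex = rep(0.5, nrow(det)),
                               dbar = rep(0, nrow(det)), year = t),
                          class = "capture_history")
  }
  names(out) <- seq_len(n_primary)
  attr(out, "truth") <- list(n_present = n_present)
  out
}
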