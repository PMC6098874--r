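# Independent individual-level micro-simulation oracle.
#
# Re-derives every transition probability from first principles (closed-form
# exponential/Weibull survival, hazard-scale risk ratios, rate-additive
# competing risks) without calling the package's hazard or Markov code, and
# simulates walkers one cycle at a time. Used to cross-validate the
# deterministic cohort engine.

microsim_occupancy <- function(s, p, lt, n_walkers, n_cycles, seed) {
  set.seed(seed)
  cl <- p$clinical
  surv <- function(lam, gamma, t) exp(-lam * t^gamma)
  cprob <- function(lam, gamma, t)
    1 - surv(lam, gamma, t + 1) / surv(lam, gamma, t)
  rate <- function(pr) -log(1 - pr)

  t_idx <- 0:(n_cycles - 1L)
  qm <- local({
    yr <- floor(p$econ$start_age + t_idx / 12)
    i <- findInterval(yr, lt$age); i[i < 1L] <- 1L
    1 - (1 - lt$qx[i])^(1 / 12)
  })
  ai_on <- if (identical(p$options$side_effect_duration, "treatment"))
    t_idx >= s$ai_start & t_idx < p$econ$therapy_months
  else t_idx >= s$ai_start

  r_bg <- rate(qm)
  r_dist <- s$rr$rr_distant *
    rate(cprob(cl$dist_distant$lam, cl$dist_distant$gamma, t_idx))
  r_loc <- s$rr$rr_local *
    rate(cprob(cl$dist_local$lam, cl$dist_local$gamma, t_idx))
  r_con <- s$rr$rr_contralateral *
    rate(cprob(cl$dist_contralateral$lam, cl$dist_contralateral$gamma, t_idx))
  r_endo <- ifelse(ai_on, s$rr$rr_endometrial, 1) * rate(cl$p_endometrial)
  r_frac <- ifelse(ai_on, s$rr$rr_fracture, 1) * rate(cl$p_fracture)
  r_prog_loc <- rate(cprob(cl$pfs_after_local$lam,
                           cl$pfs_after_local$gamma, t_idx))
  r_prog_con <- rate(cprob(cl$pfs_after_contralateral$lam,
                           cl$pfs_after_contralateral$gamma, t_idx))
  r_dd <- rate(cl$p_death_distant)
  r_de <- rate(cl$p_death_endometrial)

  # states: 1 dfs, 2 dfs+fracture, 3 local, 4 contralateral, 5 distant,
  #         6 endometrial, 7 dead
  state <- rep(1L, n_walkers)
  entry <- rep(0L, n_walkers)  # cycle of entry into state 3 or 4
  occ <- matrix(0, n_cycles + 1L, 7L)
  tally <- function() tabulate(state, 7L) / n_walkers
  occ[1L, ] <- tally()

  draw_dest <- function(idx, rates_mat, dests) {
    # rates_mat: one row per walker in idx, one column per competing exit
    total <- rowSums(rates_mat)
    p_exit <- 1 - exp(-total)
    u <- stats::runif(length(idx))
    exits <- u < p_exit & total > 0
    out <- rep(0L, length(idx))  # 0 = stay
    if (any(exits)) {
      cum <- rates_mat[exits, , drop = FALSE] /
        total[exits] * p_exit[exits]
      cum <- t(apply(cum, 1L, cumsum))
      pick <- rowSums(u[exits] > cum) + 1L
      pick[pick > length(dests)] <- length(dests)
      out[exits] <- dests[pick]
    }
    out
  }

  for (i in seq_len(n_cycles)) {
    new_state <- state
    for (st in 1:6) {
      idx <- which(state == st)
      if (!length(idx)) next
      if (st %in% c(1L, 2L)) {
        rm <- cbind(r_dist[i], r_loc[i], r_con[i], r_endo[i], r_bg[i])
        dests <- c(5L, 3L, 4L, 6L, 7L)
        if (st == 1L) { rm <- cbind(rm, r_frac[i]); dests <- c(dests, 2L) }
        rm <- rm[rep(1L, length(idx)), , drop = FALSE]
      } else if (st %in% c(3L, 4L)) {
        d <- (i - 1L) - entry[idx]
        rp <- if (st == 3L) r_prog_loc[d + 1L] else r_prog_con[d + 1L]
        rm <- cbind(rp, r_bg[i]); dests <- c(5L, 7L)
      } else {
        rr <- if (st == 5L) r_dd else r_de
        rm <- cbind(rep(rr, length(idx)), r_bg[i]); dests <- c(7L, 7L)
      }
      dest <- draw_dest(idx, rm, dests)
      moved <- dest != 0L
      new_state[idx[moved]] <- dest[moved]
      if (st %in% c(1L, 2L)) {
        into_tunnel <- moved & dest %in% c(3L, 4L)
        entry[idx[into_tunnel]] <- i  # occupied from cycle i, duration 0
      }
    }
    state <- new_state
    occ[i + 1L, ] <- tally()
  }
  colnames(occ) <- c("disease_free", "disease_free_fracture", "local",
                     "contralateral", "distant", "endometrial", "dead")
  occ
}
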