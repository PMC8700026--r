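# Shared fixtures, built once per test run.

fix <- new.env()
fix$specs <- param_specs()
fix$pset <- parameter_set(fix$specs)
fix$lt <- calibrate_life_table(73.6)

# parameter_set with selected flat values overridden
pset_with <- function(...) {
  ov <- c(...)
  v <- stats::setNames(fix$specs$mean, fix$specs$name)
  v[names(ov)] <- ov
  parameter_set(values = v)
}

# ---- independent individual-level microsimulation oracle ----------------
# Re-derives the transition law directly from the parameter values (no
# calls into the package's row builder) and pushes multinomial counts of
# n_pop individuals through it.
oracle_transition_row <- function(state, qx, pset, screened, p_detect) {
  rr_hb <- function(level) {
    unname(pset$rr["death_t2dm"]) *
      unname(pset$rr["death_per_hba1c"])^(level - unname(pset$hba1c["dx"]))
  }
  scale_p <- function(p, rr) 1 - (1 - p)^rr
  qd <- switch(state,
    NGT  = qx,
    UNDX = scale_p(qx, rr_hb(unname(pset$hba1c["undx"]))),
    DX   = scale_p(qx, unname(pset$rr["death_t2dm"])),
    COMP = scale_p(qx, rr_hb(unname(pset$hba1c["comp"]))),
    DEAD = 1)
  out <- c(NGT = 0, UNDX = 0, DX = 0, COMP = 0, DEAD = qd)
  if (state == "DEAD") return(c(NGT = 0, UNDX = 0, DX = 0, COMP = 0, DEAD = 1))
  s <- 1 - qd
  tp <- pset$tp
  if (state == "NGT") {
    out["UNDX"] <- s * tp[["ngt_undx"]]
    out["DX"] <- s * tp[["ngt_dx"]]
    out["NGT"] <- s * (1 - tp[["ngt_undx"]] - tp[["ngt_dx"]])
  } else if (state == "UNDX") {
    pdx <- if (screened) 1 - (1 - tp[["undx_dx"]]) * (1 - p_detect)
           else tp[["undx_dx"]]
    out["DX"] <- s * pdx
    out["COMP"] <- s * tp[["undx_comp"]]
    out["UNDX"] <- s * (1 - pdx - tp[["undx_comp"]])
  } else if (state == "DX") {
    out["COMP"] <- s * tp[["dx_comp"]]
    out["DX"] <- s * (1 - tp[["dx_comp"]])
  } else {
    out["COMP"] <- s
  }
  out
}

microsim_occupancy <- function(n_pop, start_age, pset, lt,
                               strategy = NULL, seed = 1L) {
  set.seed(seed)
  states <- c("NGT", "UNDX", "DX", "COMP", "DEAD")
  max_age <- max(lt$age)
  n_cycles <- max_age - start_age + 1L
  screen_set <- if (is.null(strategy)) integer(0)
    else screening_cycles(strategy$interval, n_cycles)
  p_detect <- if (is.null(strategy)) 0
    else detection_probability(strategy, pset)
  prev_ages <- as.numeric(names(pset$prevalence))
  prev <- stats::approx(prev_ages, unname(pset$prevalence),
                        xout = start_age, rule = 2)$y
  counts <- stats::setNames(as.vector(stats::rmultinom(
    1, n_pop, c(1 - prev, prev, 0, 0, 0))), states)
  occ <- matrix(0, n_cycles + 1L, 5L, dimnames = list(0:n_cycles, states))
  occ[1L, ] <- counts / n_pop
  for (t in 0:(n_cycles - 1L)) {
    qx <- lt$qx[match(start_age + t, lt$age)]
    nxt <- stats::setNames(numeric(5), states)
    for (s in states) {
      if (counts[[s]] == 0) next
      p <- oracle_transition_row(s, qx, pset, t %in% screen_set, p_detect)
      nxt <- nxt + as.vector(stats::rmultinom(1, counts[[s]], p))
    }
    counts <- nxt
    occ[t + 2L, ] <- counts / n_pop
  }
  occ
}
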