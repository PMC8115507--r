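# Shared fixtures, built in code. The default-scale simulation is memoised
# because several files exercise it end to end.

.fixtures <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim <- simulate_scenarios(default_config())
  }
  .fixtures$sim
}

# Minimal cube constructor for hand-built series and random fields.
toy_cube <- function(values, cls = "sat_cube", start = "2018-01-01",
                     scenario = "toy", theta = NULL) {
  if (is.null(dim(values))) {
    values <- array(values, dim = c(1L, 1L, length(values)))
  }
  dates <- seq(as.Date(start), by = "day", length.out = dim(values)[3])
  out <- structure(
    list(values = values, dates = dates, scenario_label = scenario),
    class = c(cls, "pondwi_cube")
  )
  if (!is.null(theta)) out$theta <- theta
  out
}

random_sat_cube <- function(nr, nc, nt, seed, start = "2018-01-01") {
  set.seed(seed)
  toy_cube(array(runif(nr * nc * nt), dim = c(nr, nc, nt)), start = start)
}

# Independent run-length oracle for the wetness index: expands the runs of
# the boolean ponding series rather than iterating the recurrence.
wi_oracle_series <- function(ponded) {
  r <- rle(as.logical(ponded))
  unlist(lapply(seq_along(r$lengths), function(i) {
    if (r$values[i]) seq_len(r$lengths[i]) else rep(0L, r$lengths[i])
  }), use.names = FALSE)
}

wi_oracle_cube <- function(sat, theta) {
  d <- dim(sat$values)
  out <- array(0L, dim = d)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      out[i, j, ] <- wi_oracle_series(sat$values[i, j, ] >= theta)
    }
  }
  out
}

# Walks every cell downstream; returns FALSE if any walk revisits a cell.
acyclic_flow <- function(domain) {
  ds <- pondwi:::downslope_index(domain$flow_dir)
  n <- length(ds)
  for (start in seq_len(n)) {
    cur <- start
    steps <- 0L
    while (!is.na(ds[cur])) {
      cur <- ds[cur]
      steps <- steps + 1L
      if (steps > n) return(FALSE)
    }
  }
  TRUE
}
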