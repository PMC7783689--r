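# independent agent-based microsimulation oracle: simulates n_agents discrete
# individuals through the same one-cycle matrices the cohort engine uses, and
# returns state counts per age
microsimulate <- function(n_agents, spec, schedule, lifetable, hrs, sex,
                          seed) {
  set.seed(seed)
  states <- bmicohort:::STATES
  ages <- spec$start_age:spec$end_age
  init <- c(spec$init[["NW"]], 0, spec$init[["OW"]], spec$init[["OB1"]],
            spec$init[["OB2"]], 0)
  s <- sample.int(6, n_agents, replace = TRUE, prob = init)
  counts <- matrix(0L, nrow = 6, ncol = length(ages),
                   dimnames = list(states, ages))
  counts[, 1] <- tabulate(s, 6)
  for (i in seq_len(length(ages) - 1)) {
    M <- assemble_matrix(ages[i], sex, schedule, lifetable, hrs)
    u <- runif(n_agents)
    snew <- s
    for (st in unique(s)) {
      grp <- s == st
      snew[grp] <- findInterval(u[grp], cumsum(M[st, ]),
                                rightmost.closed = TRUE) + 1L
    }
    s <- snew
    counts[, i + 1] <- tabulate(s, 6)
  }
  counts
}
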