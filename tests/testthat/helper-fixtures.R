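# Small, fast fixtures built in code.

short_gen_params <- function(seed, duration_s = 600, n_events = 2,
                             event_range = c(60, 90), ...) {
  generator_params(duration_s = duration_s, n_events = n_events,
                   event_duration_range_s = event_range, seed = seed, ...)
}

make_cohort <- function(n = 3, seed = 1, duration_s = 600, n_events = 2) {
  lapply(seq_len(n), function(i)
    generate_participant(short_gen_params(seed * 1000 + i,
                                          duration_s = duration_s,
                                          n_events = n_events),
                         participant_id = paste0("P", i)))
}

# random small design space for enumeration property tests
random_space <- function(seed) {
  set.seed(seed)
  nf <- sample(1:3, 1)
  design_space(lapply(seq_len(nf), function(f) {
    ncomp <- sample(1:3, 1)
    functionality(paste0("F", f), lapply(seq_len(ncomp), function(q) {
      npar <- sample(0:2, 1)
      params <- if (npar > 0) {
        ps <- lapply(seq_len(npar), function(w) sample(1:9, sample(1:4, 1)))
        names(ps) <- paste0("p", seq_len(npar))
        ps
      } else list()
      component_spec(paste0("F", f, "C", q), params = params)
    }))
  }))
}

random_metric_vector <- function() {
  metric_vector(P = runif(1), R = runif(1), ET = runif(1, 0, 10),
                EC = runif(1, 0, 100), MD = runif(1, 0, 1e5),
                CL = runif(1, 0, 5))
}

# independent all-pairs dominance oracle on plain numeric vectors
oracle_front <- function(vectors) {
  better <- function(a, b) {
    av <- c(a[["P"]], a[["R"]], -a[["ET"]], -a[["EC"]], -a[["MD"]], -a[["CL"]])
    bv <- c(b[["P"]], b[["R"]], -b[["ET"]], -b[["EC"]], -b[["MD"]], -b[["CL"]])
    all(av >= bv) && any(av > bv)
  }
  keep <- vapply(seq_along(vectors), function(i)
    !any(vapply(seq_along(vectors), function(j)
      j != i && better(vectors[[j]], vectors[[i]]), logical(1))),
    logical(1))
  vectors[keep]
}
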