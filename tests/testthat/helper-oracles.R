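# Independent oracles, deliberately naive: exhaustive path enumeration for
# the decoder and per-base counting for recurrent regions.

# A random model with valid shapes but arbitrary probabilities; only the
# matrices matter for decoding.
random_hmm <- function() {
  states <- upd_states()
  simplex <- function(n) {
    x <- runif(n) + 1e-3
    x / sum(x)
  }
  trans <- t(replicate(5, simplex(5)))
  dimnames(trans) <- list(states, states)
  emis <- matrix(runif(5 * 27) + 1e-4, 5, 27,
                 dimnames = list(states, as.character(0:26)))
  structure(
    list(states = states,
         log_initial = setNames(log(simplex(5)), states),
         log_transition = log(trans),
         log_emission = log(emis),
         epsilon = NA_real_, tau = NA_real_),
    class = "upd_hmm"
  )
}

# Enumerate all 5^n joint paths; returns the best path (1-based state
# indices) and its log joint probability.
brute_force_viterbi <- function(model, obs) {
  n <- length(obs)
  if (n == 0L) return(list(path = integer(0), log_joint = 0))
  S <- length(model$states)
  lp <- model$log_initial + model$log_emission[, obs[1] + 1L]
  last <- 1:S
  for (t in seq_len(n)[-1]) {
    L <- length(lp)
    lp <- unlist(lapply(1:S, function(j) {
      lp + model$log_transition[cbind(last, j)] +
        model$log_emission[j, obs[t] + 1L]
    }))
    last <- rep(1:S, each = L)
  }
  k <- which.max(lp) - 1L
  path <- integer(n)
  for (t in seq_len(n)) {
    path[t] <- k %% S + 1L
    k <- k %/% S
  }
  list(path = path, log_joint = max(lp))
}

# Plain-R dynamic-programming decoder (no shared code with src/), for
# sequences too long to enumerate.
r_viterbi <- function(model, obs) {
  n <- length(obs)
  S <- length(model$states)
  if (n == 0L) return(list(path = integer(0), log_joint = 0))
  delta <- model$log_initial + model$log_emission[, obs[1] + 1L]
  back <- matrix(0L, n, S)
  for (t in seq_len(n)[-1]) {
    m <- delta + model$log_transition
    arg <- apply(m, 2, which.max)
    delta <- m[cbind(arg, 1:S)] + model$log_emission[, obs[t] + 1L]
    back[t, ] <- arg
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  for (t in n:2) path[t - 1L] <- back[t, path[t]]
  list(path = path, log_joint = max(delta))
}

# Per-base distinct-sample counting on small instances.
brute_force_recurrent <- function(events, min_samples) {
  out <- list()
  for (ch in unique(events$chrom)) {
    e <- events[events$chrom == ch, ]
    span <- max(e$end)
    n_at <- vapply(seq_len(span), function(b) {
      length(unique(e$sample_id[e$start <= b & e$end >= b]))
    }, integer(1))
    ok <- n_at >= min_samples
    if (!any(ok)) next
    r <- rle(ok)
    last <- cumsum(r$lengths)
    first <- last - r$lengths + 1L
    for (j in which(r$values)) {
      n <- length(unique(
        e$sample_id[e$start <= last[j] & e$end >= first[j]]))
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = ch, start = first[j], end = last[j], n_samples = n)
    }
  }
  if (!length(out))
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_samples = integer()))
  dplyr::arrange(dplyr::bind_rows(out), chrom, start)
}
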