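# Independent brute-force reimplementation of the analysis semantics
# (group -> sort -> pair -> tally -> divide), written with plain loops
# and base R only. It shares no code with the package internals and is
# the oracle the pipeline is compared against.

# consecutive within-season pairs from a cleaned record table
bf_pairs <- function(df) {
  from <- integer(0)
  to <- integer(0)
  for (pid in unique(df$player_id)) {
    for (season in unique(df$season_label[df$player_id == pid])) {
      idx <- which(df$player_id == pid & df$season_label == season)
      idx <- idx[order(df$injury_date[idx], df$.row[idx])]
      if (length(idx) >= 2) {
        for (k in 1:(length(idx) - 1)) {
          from <- c(from, idx[k])
          to <- c(to, idx[k + 1])
        }
      }
    }
  }
  list(from = from, to = to)
}

bf_state <- function(df, idx) {
  paste(df$body_part[idx], df$nature[idx], sep = " : ")
}

# tally pairs into a named count matrix
bf_count_matrix <- function(from_states, to_states) {
  states <- sort(unique(c(from_states, to_states)))
  m <- matrix(0L, length(states), length(states),
              dimnames = list(states, states))
  for (k in seq_along(from_states)) {
    m[from_states[k], to_states[k]] <- m[from_states[k], to_states[k]] + 1L
  }
  m
}

bf_probs <- function(m, denominator) {
  if (denominator == "global") {
    m / sum(m)
  } else {
    out <- m
    for (i in seq_len(nrow(m))) {
      rs <- sum(m[i, ])
      out[i, ] <- if (rs > 0) m[i, ] / rs else NA_real_
    }
    out
  }
}

# full brute-force analysis of a cleaned record set; returns the count
# matrix and both probability conventions
bf_analysis <- function(records_clean) {
  df <- as.data.frame(records_clean)
  pr <- bf_pairs(df)
  from_states <- bf_state(df, pr$from)
  to_states <- bf_state(df, pr$to)
  m <- bf_count_matrix(from_states, to_states)
  list(counts = m, total = length(pr$from),
       global = bf_probs(m, "global"), row = bf_probs(m, "row"))
}
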