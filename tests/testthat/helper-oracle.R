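# Independent brute-force classifier: walks follow-up months one at a time,
# re-scanning the episode list for the current expectation window at every
# month. Deliberately naive so it shares no code path with classify_months().
oracle_classify <- function(episodes, end, config = eic_rule_config()) {
  ep <- as.data.frame(episodes)
  cols <- as.list(ep)
  N <- vapply(seq_len(nrow(ep)), function(i)
    expected_interval(lapply(cols, `[[`, i), config)$months, numeric(1))
  labels <- character(end)
  anchors <- integer(end)
  for (t in seq_len(end)) {
    anchor <- NA_integer_
    for (i in seq_len(nrow(ep))) {          # brute-force scan every month
      if (ep$month_index[i] < t) anchor <- i
    }
    labels[t] <- if (t <= ep$month_index[anchor] + N[anchor]) "in_care" else
      "out_of_care"
    anchors[t] <- ep$month_index[anchor]
  }
  list(month_index = seq_len(end), label = labels,
       anchor_episode_month = anchors)
}
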