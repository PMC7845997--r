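# Shared test utilities: a deterministic random-expression generator and a
# hand-built toy trial table.

random_expression <- function(depth = 3) {
  kind <- if (depth <= 0) "atom" else
    sample(c("atom", "repeat", "concat"), 1, prob = c(0.4, 0.35, 0.25))
  switch(kind,
    atom = lot_atom(sample(c("stay", "flip"), 1)),
    `repeat` = lot_repeat(random_expression(depth - 1),
                          sample(1:9, 1),
                          transform = sample(list(NULL, "stay", "flip"), 1)[[1]]),
    concat = lot_concat(lapply(seq_len(sample(2:3, 1)), function(i)
      random_expression(depth - 1))))
}

# one participant x sequence block: nd deviant trials (all at position `pos`)
# and ns standards, with explicit outcomes
toy_block <- function(participant, sequence_id, pattern, rts, miss = 0,
                      fa = 0, ns = 6, pos = 5, deviant_type = "sequence",
                      experiment = "toy", modality = "auditory") {
  nd <- length(rts) + miss
  dev <- data.frame(
    participant = participant, experiment = experiment, modality = modality,
    sequence_id = sequence_id, pattern = pattern, trial = seq_len(nd),
    deviant_type = deviant_type, deviant_position = pos,
    responded = c(rep(TRUE, length(rts)), rep(FALSE, miss)),
    rt_ms = c(rts, rep(NA_real_, miss)), stringsAsFactors = FALSE)
  if (ns == 0) return(dev)
  std <- data.frame(
    participant = participant, experiment = experiment, modality = modality,
    sequence_id = sequence_id, pattern = pattern, trial = nd + seq_len(ns),
    deviant_type = "none", deviant_position = NA_integer_,
    responded = seq_len(ns) <= fa,
    rt_ms = ifelse(seq_len(ns) <= fa, 700, NA_real_),
    stringsAsFactors = FALSE)
  rbind(dev, std)
}
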