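#' @title Trial-level behavioral scoring
#'
#' @description Turns raw deviant-detection trial tables into per-sequence
#' performance scores: outcome classification against the 200-2500 ms hit
#' window, response-time trimming at 2.5 SD around the per-cell median,
#' the Linear Integrated Speed-Accuracy Score (LISAS), false-alarm counts
#' and median+2.5 SD participant exclusion.
#'
#' A trial table is a data.frame with columns `participant` (id),
#' `experiment`, `modality` (`"auditory"`/`"visual"`), `sequence_id`,
#' `pattern`, `trial` (index), `deviant_type`
#' (`"none"`, `"sequence"`, `"super"`), `deviant_position` (1-based, `NA`
#' for standards), `responded` (logical) and `rt_ms` (latency from deviant
#' onset, `NA` when no response).
#' @name behavior_metrics
NULL

.trial_cols <- c("participant", "experiment", "modality", "sequence_id",
                 "pattern", "trial", "deviant_type", "deviant_position",
                 "responded", "rt_ms")

.check_trials <- function(trials) {
  miss <- setdiff(.trial_cols, names(trials))
  if (length(miss))
    stop("trial table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(trials$deviant_type %in% c("none", "sequence", "super")))
    stop("deviant_type must be none/sequence/super", call. = FALSE)
  bad <- trials$deviant_type != "none" & is.na(trials$deviant_position)
  if (any(bad))
    stop("deviant trials must carry a deviant_position", call. = FALSE)
  invisible(trials)
}

#' Classify trial outcomes
#'
#' Deviant trials: a response with latency inside `window` (default
#' 200-2500 ms from deviant onset) is a `hit`, anything else a `miss`.
#' Standard trials: any response is a `false_alarm`, none a
#' `correct_rejection`. Rows with a negative recorded latency are dropped
#' with a warning. Classification is exhaustive and exclusive.
#'
#' @param trials A trial table (see [behavior_metrics]).
#' @param window Numeric length-2 hit window in ms.
#' @return The trial table with an `outcome` factor column added.
#' @export
classify_trials <- function(trials, window = c(200, 2500)) {
  .check_trials(trials)
  neg <- !is.na(trials$rt_ms) & trials$rt_ms < 0
  if (any(neg)) {
    warning(sprintf("dropping %d trial(s) with negative RT", sum(neg)))
    trials <- trials[!neg, , drop = FALSE]
  }
  deviant <- trials$deviant_type != "none"
  in_window <- trials$responded & !is.na(trials$rt_ms) &
    trials$rt_ms >= window[1] & trials$rt_ms <= window[2]
  out <- ifelse(deviant,
                ifelse(in_window, "hit", "miss"),
                ifelse(trials$responded, "false_alarm", "correct_rejection"))
  trials$outcome <- factor(out, levels = c("hit", "miss", "false_alarm",
                                           "correct_rejection"))
  trials
}

#' Trim extreme response times
#'
#' Within each (participant x sequence x deviant type) cell, hit RTs further
#' than `k` sample SDs from the cell median are flagged `rt_trimmed` and
#' excluded from RT statistics only -- the trial stays a hit for miss-rate
#' purposes, keeping miss rate a pure detection measure. The SD for each
#' candidate is computed over the *other* RTs of its cell (leave-one-out),
#' so a single extreme response cannot mask itself by inflating the cell SD.
#' Cells with fewer than three RTs (no leave-one-out SD) pass through
#' untrimmed.
#'
#' @param trials A classified trial table.
#' @param k SD multiplier (default 2.5).
#' @return `list(trials = <table with rt_trimmed column>, fraction =
#'   <share of hit RTs removed>)`.
#' @export
trim_rts <- function(trials, k = 2.5) {
  stopifnot("outcome" %in% names(trials))
  trials$rt_trimmed <- FALSE
  hit <- which(trials$outcome == "hit")
  if (!length(hit)) return(list(trials = trials, fraction = 0))
  cell <- interaction(trials$participant[hit], trials$sequence_id[hit],
                      trials$deviant_type[hit], drop = TRUE)
  for (cl in levels(cell)) {
    idx <- hit[cell == cl]
    if (length(idx) < 3L) next
    rts <- trials$rt_ms[idx]
    md <- stats::median(rts)
    for (q in seq_along(idx)) {
      s <- stats::sd(rts[-q])
      if (is.na(s)) next
      if (abs(rts[q] - md) > k * s) trials$rt_trimmed[idx[q]] <- TRUE
    }
  }
  list(trials = trials,
       fraction = sum(trials$rt_trimmed) / length(hit))
}

#' Linear Integrated Speed-Accuracy Score
#'
#' `LISAS = RT_c + MR * S_RT / S_MR`: the mean correct response time plus the
#' miss rate scaled by the ratio of the participant's overall RT standard
#' deviation to their overall miss-indicator standard deviation, which
#' expresses accuracy on the response-time scale (ms).
#'
#' @param rt_c Mean correct RT (ms).
#' @param mr Miss rate in `[0, 1]`.
#' @param s_rt Participant's overall RT standard deviation (ms).
#' @param s_mr Participant's overall miss-indicator standard deviation.
#' @return Score in ms; `rt_c` exactly when `mr = 0`. `s_mr = 0` with a
#'   positive miss rate is an error.
#' @examples
#' lisas(600, 0.2, 100, 0.1)  # 800
#' @export
lisas <- function(rt_c, mr, s_rt, s_mr) {
  stopifnot(rt_c >= 0, mr >= 0, mr <= 1, s_rt >= 0, s_mr >= 0)
  if (mr == 0) return(rt_c)
  if (s_mr == 0)
    stop("s_mr = 0 with a positive miss rate: LISAS undefined", call. = FALSE)
  rt_c + mr * s_rt / s_mr
}

#' Exclude outlier participants
#'
#' A participant is excluded when any of their mean miss rate, mean RT or
#' mean false-alarm count strictly exceeds the group median plus `k` times
#' the group SD of that quantity (SD taken around the group median). Ties at
#' the threshold are kept.
#'
#' @param summary A data.frame with columns `participant`, `miss_rate`,
#'   `mean_rt`, `false_alarms` (one row per participant, >= 3 rows).
#' @param k SD multiplier (default 2.5).
#' @return `list(kept, excluded, reasons)` where `reasons` is a data.frame
#'   of participant/criterion pairs.
#' @export
exclude_participants <- function(summary, k = 2.5) {
  need <- c("participant", "miss_rate", "mean_rt", "false_alarms")
  miss <- setdiff(need, names(summary))
  if (length(miss))
    stop("summary lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(summary) < 3L)
    stop("need at least 3 participants", call. = FALSE)
  sd_about_median <- function(x) {
    md <- stats::median(x)
    sqrt(sum((x - md)^2) / (length(x) - 1L))
  }
  reasons <- data.frame(participant = character(0), criterion = character(0),
                        stringsAsFactors = FALSE)
  for (crit in c("miss_rate", "mean_rt", "false_alarms")) {
    v <- summary[[crit]]
    thr <- stats::median(v) + k * sd_about_median(v)
    over <- v > thr
    if (any(over))
      reasons <- rbind(reasons, data.frame(
        participant = as.character(summary$participant[over]),
        criterion = crit, stringsAsFactors = FALSE))
  }
  excluded <- unique(reasons$participant)
  list(kept = setdiff(as.character(summary$participant), excluded),
       excluded = excluded, reasons = reasons)
}

#' Per-sequence performance scores with predictors
#'
#' Aggregates classified, trimmed trials into one row per
#' (participant x sequence x deviant type): mean correct RT (after
#' trimming), miss rate, LISAS (using the participant's overall deviant-trial
#' S_RT and S_MR), false-alarm count from the sequence's standard trials, and
#' joins the complexity metrics (by canonical `pattern`) and, when supplied,
#' a per-sequence mean surprise table. Rows whose predictors are missing are
#' flagged via `predictors_missing`, not dropped.
#'
#' @param trials A classified trial table ([classify_trials()]), ideally
#'   after [trim_rts()].
#' @param metrics A [sequence_metrics()] table.
#' @param surprise Optional data.frame with columns `pattern` and
#'   `surprise` (mean deviant surprise per sequence).
#' @return A data.frame of scores and predictors.
#' @export
sequence_scores <- function(trials, metrics = NULL, surprise = NULL) {
  stopifnot("outcome" %in% names(trials))
  if (!"rt_trimmed" %in% names(trials)) trials$rt_trimmed <- FALSE
  trials$pattern <- canonicalize_sequence(trials$pattern)

  dev <- trials[trials$deviant_type != "none", , drop = FALSE]
  # participant-level overall SDs across all their deviant trials
  sds <- do.call(rbind, lapply(split(dev, dev$participant), function(d) {
    rts <- d$rt_ms[d$outcome == "hit" & !d$rt_trimmed]
    data.frame(participant = d$participant[1L],
               s_rt = if (length(rts) >= 2L) stats::sd(rts) else NA_real_,
               s_mr = stats::sd(as.integer(d$outcome == "miss")),
               stringsAsFactors = FALSE)
  }))

  key <- interaction(dev$participant, dev$sequence_id, dev$deviant_type,
                     drop = TRUE)
  rows <- lapply(split(dev, key), function(d) {
    hits <- d$outcome == "hit"
    rts <- d$rt_ms[hits & !d$rt_trimmed]
    rt_c <- if (length(rts)) mean(rts) else NA_real_
    mr <- mean(d$outcome == "miss")
    p <- as.character(d$participant[1L])
    s <- sds[sds$participant == p, ]
    sc <- if (is.na(rt_c)) NA_real_
          else if (mr == 0) rt_c
          else if (is.na(s$s_rt) || is.na(s$s_mr) || s$s_mr == 0) NA_real_
          else lisas(rt_c, mr, s$s_rt, s$s_mr)
    data.frame(participant = p, experiment = d$experiment[1L],
               modality = d$modality[1L], sequence_id = d$sequence_id[1L],
               pattern = d$pattern[1L], deviant_type = as.character(d$deviant_type[1L]),
               n_trials = nrow(d), rt_c = rt_c, miss_rate = mr, lisas = sc,
               stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  std <- trials[trials$deviant_type == "none", , drop = FALSE]
  fa <- stats::aggregate(list(false_alarms = std$outcome == "false_alarm"),
                         by = list(participant = std$participant,
                                   sequence_id = std$sequence_id),
                         FUN = sum)
  scores <- merge(scores, fa, by = c("participant", "sequence_id"),
                  all.x = TRUE, sort = FALSE)

  if (!is.null(metrics)) {
    scores <- merge(scores, metrics, by = "pattern", all.x = TRUE,
                    sort = FALSE)
    scores$predictors_missing <- is.na(scores$lot)
    if (any(scores$predictors_missing))
      warning(sprintf("%d score row(s) have no metric entry for their pattern",
                      sum(scores$predictors_missing)))
  }
  if (!is.null(surprise)) {
    surprise$pattern <- canonicalize_sequence(surprise$pattern)
    scores <- merge(scores, surprise[, c("pattern", "surprise")],
                    by = "pattern", all.x = TRUE, sort = FALSE)
  }
  scores[order(scores$participant, scores$sequence_id, scores$deviant_type), ,
         drop = FALSE]
}
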