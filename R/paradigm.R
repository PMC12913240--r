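#' Paradigm configuration for a paired-stimulus local-global session
#'
#' Describes one session of the paired-stimulus local-global auditory oddball
#' paradigm. Every pair starts with a 1000-Hz standard tone (S); the second
#' stimulus is S again (S-S pair), a 1500-Hz frequency deviant (S-F pair), or a
#' spoken-numeral train deviant (S-T pair). An initial block of S-S pairs
#' establishes the regularity and is excluded from analysis. S-T pairs are the
#' global deviants; each one is classified by the type of the homogeneous run
#' of pairs immediately preceding it (S-S context or S-F context).
#'
#' Defaults reproduce the published session: 1380 pairs total, 30 regularity
#' pairs, 555/540/255 analyzed S-S/S-F/S-T pairs (so S-T pairs are 18.89% of
#' analyzed pairs), 121 S-T pairs in S-S context and 134 in S-F context, at
#' least 3 intervening pairs between consecutive S-T pairs, 350-ms within-pair
#' onset asynchrony, 200-ms stimuli, and an inter-pair interval jittered over
#' 1000-1300 ms in 50-ms steps (measured from the offset of the second
#' stimulus to the onset of the next pair, which yields the published ~40-min
#' session).
#'
#' @param n_total_pairs Total pairs in the session, including the regularity
#'   block.
#' @param n_regularity_pairs Leading S-S pairs establishing the regularity
#'   (flagged `analyzed = FALSE`).
#' @param n_ss,n_sf,n_st Analyzed S-S, S-F and S-T pair counts. Must sum to
#'   `n_total_pairs - n_regularity_pairs`.
#' @param n_st_context_ss,n_st_context_sf How many S-T pairs sit in an S-S vs
#'   an S-F context. Must sum to `n_st`.
#' @param min_intervening_pairs Minimum number of non-S-T pairs between
#'   consecutive S-T pairs; the same number of pairs immediately before each
#'   S-T pair is forced to its context type, so the disrupted regularity is
#'   well defined.
#' @param soa_within_pair_ms Onset asynchrony between the two stimuli of a
#'   pair (ms).
#' @param iti_min_ms,iti_max_ms,iti_step_ms Jitter grid for the inter-pair
#'   interval (ms), measured offset-of-second-stimulus to onset-of-next-pair.
#' @param stimulus_duration_ms Stimulus duration (ms).
#' @param numeral_set Identifiers for the train-deviant tokens (spoken
#'   numerals "one".."nine" in the published design; audio itself is out of
#'   scope, these are labels only).
#'
#' @return A `lg_paradigm_config` list.
#' @export
#' @examples
#' cfg <- paradigm_config()
#' cfg$n_ss + cfg$n_sf + cfg$n_st   # 1350 analyzed pairs
paradigm_config <- function(n_total_pairs = 1380L,
                            n_regularity_pairs = 30L,
                            n_ss = 555L,
                            n_sf = 540L,
                            n_st = 255L,
                            n_st_context_ss = 121L,
                            n_st_context_sf = 134L,
                            min_intervening_pairs = 3L,
                            soa_within_pair_ms = 350,
                            iti_min_ms = 1000,
                            iti_max_ms = 1300,
                            iti_step_ms = 50,
                            stimulus_duration_ms = 200,
                            numeral_set = paste0("T", 1:9)) {
  cfg <- list(
    n_total_pairs = as.integer(n_total_pairs),
    n_regularity_pairs = as.integer(n_regularity_pairs),
    n_ss = as.integer(n_ss), n_sf = as.integer(n_sf), n_st = as.integer(n_st),
    n_st_context_ss = as.integer(n_st_context_ss),
    n_st_context_sf = as.integer(n_st_context_sf),
    min_intervening_pairs = as.integer(min_intervening_pairs),
    soa_within_pair_ms = soa_within_pair_ms,
    iti_min_ms = iti_min_ms, iti_max_ms = iti_max_ms,
    iti_step_ms = iti_step_ms,
    stimulus_duration_ms = stimulus_duration_ms,
    numeral_set = as.character(numeral_set)
  )
  class(cfg) <- "lg_paradigm_config"
  validate_paradigm_config(cfg)
  cfg
}

validate_paradigm_config <- function(cfg) {
  counts <- c(cfg$n_total_pairs, cfg$n_regularity_pairs, cfg$n_ss, cfg$n_sf,
              cfg$n_st, cfg$n_st_context_ss, cfg$n_st_context_sf,
              cfg$min_intervening_pairs)
  if (any(counts < 0)) stopf("all paradigm counts must be >= 0")
  n_an <- cfg$n_total_pairs - cfg$n_regularity_pairs
  if (cfg$n_ss + cfg$n_sf + cfg$n_st != n_an)
    stopf("n_ss + n_sf + n_st (%d) must equal n_total_pairs - n_regularity_pairs (%d)",
          cfg$n_ss + cfg$n_sf + cfg$n_st, n_an)
  if (cfg$n_st_context_ss + cfg$n_st_context_sf != cfg$n_st)
    stopf("context counts (%d + %d) must sum to n_st (%d)",
          cfg$n_st_context_ss, cfg$n_st_context_sf, cfg$n_st)
  if (cfg$iti_max_ms < cfg$iti_min_ms)
    stopf("iti_max_ms must be >= iti_min_ms")
  if (cfg$iti_step_ms <= 0 ||
      abs((cfg$iti_max_ms - cfg$iti_min_ms) %% cfg$iti_step_ms) > 1e-9)
    stopf("inter-pair interval range must be divisible by iti_step_ms")
  if (cfg$n_st > 0 && length(cfg$numeral_set) == 0)
    stopf("numeral_set must be non-empty when n_st > 0")
  invisible(cfg)
}

#' Generate one session's event schedule
#'
#' Produces the full, exactly-counted event list for one session. S-T pairs
#' are placed uniformly at random among all placements satisfying the
#' separation constraint (at least `min_intervening_pairs` non-S-T pairs
#' between consecutive S-T pairs, and before the first one). The
#' `min_intervening_pairs` pairs immediately preceding each S-T pair are set
#' to that pair's context type (S-S or S-F), so every global deviant disrupts
#' a well-defined homogeneous run; remaining slots are filled by a random
#' permutation of the leftover S-S/S-F pairs. Composition counts are exact,
#' never probabilistic.
#'
#' The active and passive sessions built from the same seed carry identical
#' event lists; only the `condition` label differs (the published design
#' presents identical auditory stimulation under both task conditions).
#'
#' @param config A [paradigm_config()].
#' @param condition `"active"` or `"passive"` (task label only).
#' @param seed Integer seed; identical seed + config reproduce the schedule
#'   byte for byte.
#'
#' @return A tibble of class `lg_schedule`, two rows per pair, with columns
#'   `onset_ms`, `stimulus_code` (`"S"`, `"F"`, or a numeral token),
#'   `pair_index`, `position` (`"first"`/`"second"`), `pair_type`
#'   (`"SS"`/`"SF"`/`"ST"`), `global_context` (`"SS"`/`"SF"` on the second
#'   stimulus of S-T pairs, `NA` elsewhere) and `analyzed`.
#' @export
#' @examples
#' sch <- generate_session(paradigm_config(n_total_pairs = 64,
#'   n_regularity_pairs = 4, n_ss = 25, n_sf = 23, n_st = 12,
#'   n_st_context_ss = 6, n_st_context_sf = 6), "passive", seed = 1)
#' table(sch$pair_type[sch$position == "first" & sch$analyzed]) / 1
generate_session <- function(config, condition = c("active", "passive"),
                             seed = NULL) {
  condition <- match.arg(condition)
  validate_paradigm_config(config)
  n_an <- config$n_total_pairs - config$n_regularity_pairs
  if (n_an <= 0) stopf("schedule has zero analyzed pairs")
  m <- config$min_intervening_pairs

  with_seed(seed, {
    types <- generate_pair_types(config, n_an, m)
    n_pairs <- config$n_regularity_pairs + n_an
    pair_type <- c(rep("SS", config$n_regularity_pairs), types$type)
    context <- c(rep(NA_character_, config$n_regularity_pairs), types$context)
    analyzed <- c(rep(FALSE, config$n_regularity_pairs), rep(TRUE, n_an))

    second_code <- character(n_pairs)
    second_code[pair_type == "SS"] <- "S"
    second_code[pair_type == "SF"] <- "F"
    if (any(pair_type == "ST"))
      second_code[pair_type == "ST"] <-
        sample_vec(config$numeral_set, sum(pair_type == "ST"), replace = TRUE)

    gc_col <- ifelse(rep(pair_type, each = 2) == "ST" &
                       rep(c(FALSE, TRUE), n_pairs),
                     rep(context, each = 2), NA_character_)
    events <- tibble(
      onset_ms = NA_real_,
      stimulus_code = as.vector(rbind("S", second_code)),
      pair_index = rep(seq_len(n_pairs), each = 2),
      position = rep(c("first", "second"), n_pairs),
      pair_type = rep(pair_type, each = 2),
      global_context = gc_col,
      analyzed = rep(analyzed, each = 2)
    )
    events <- assign_onsets(events, config)
    attr(events, "condition") <- condition
    attr(events, "config") <- config
    class(events) <- c("lg_schedule", class(events))
    events
  })
}

# Draw the per-pair type sequence for the analyzed block. Placement of the
# n_st S-T pairs is uniform over all sequences with pairwise index gaps
# >= m + 1 (and first position > m), via the standard gap transform:
# strictly increasing z in 1..(n_an - m * n_st) maps to positions z_i + m * i.
generate_pair_types <- function(config, n_an, m) {
  n_st <- config$n_st
  type <- rep(NA_character_, n_an)
  context <- rep(NA_character_, n_an)

  if (n_st > 0) {
    slack <- n_an - m * n_st
    if (slack < n_st)
      stopf("infeasible schedule: n_st * (min_intervening_pairs + 1) = %d exceeds %d analyzed pairs",
            n_st * (m + 1), n_an)
    z <- sort(sample.int(slack, n_st))
    st_pos <- z + m * seq_len(n_st)
    ctx <- sample_vec(c(rep("SS", config$n_st_context_ss),
                        rep("SF", config$n_st_context_sf)))
    type[st_pos] <- "ST"
    context[st_pos] <- ctx
    # Force the m pairs before each S-T pair to its context type; runs that
    # would extend before the analyzed block lean on the S-S regularity block.
    forced_ss <- 0L; forced_sf <- 0L
    for (i in seq_len(n_st)) {
      run <- seq.int(max(1L, st_pos[i] - m), st_pos[i] - 1L)
      run <- run[is.na(type[run])]
      type[run] <- if (ctx[i] == "SS") "SS" else "SF"
      if (ctx[i] == "SS") forced_ss <- forced_ss + length(run)
      else forced_sf <- forced_sf + length(run)
      if (st_pos[i] - m < 1L && ctx[i] == "SF")
        stopf("infeasible schedule: an S-F-context S-T pair falls inside the first %d pairs", m)
    }
    free_ss <- config$n_ss - forced_ss
    free_sf <- config$n_sf - forced_sf
    if (free_ss < 0 || free_sf < 0)
      stopf("infeasible schedule: context runs require %d S-S and %d S-F pairs but only %d / %d are configured",
            forced_ss, forced_sf, config$n_ss, config$n_sf)
    fill <- sample_vec(c(rep("SS", free_ss), rep("SF", free_sf)))
  } else {
    fill <- sample_vec(c(rep("SS", config$n_ss), rep("SF", config$n_sf)))
  }
  type[is.na(type)] <- fill
  list(type = type, context = context)
}

#' Assign stimulus onsets to an ordered schedule
#'
#' Within a pair the second stimulus starts exactly `soa_within_pair_ms` after
#' the first. Between pairs, a jitter drawn uniformly from the configured grid
#' (`iti_min_ms`, `iti_min_ms + iti_step_ms`, ..., `iti_max_ms`) separates the
#' offset of one pair's second stimulus from the onset of the next pair. The
#' first stimulus of the session is at 0 ms.
#'
#' @param events Event tibble in pair order (two rows per pair); any existing
#'   onsets are overwritten.
#' @param config A [paradigm_config()] supplying the timing parameters.
#' @return The event tibble with `onset_ms` filled in.
#' @export
assign_onsets <- function(events, config) {
  n_pairs <- max(events$pair_index)
  grid <- seq(config$iti_min_ms, config$iti_max_ms, by = config$iti_step_ms)
  iti <- if (n_pairs > 1) sample_vec(grid, n_pairs - 1, replace = TRUE) else numeric(0)
  pair_period <- config$soa_within_pair_ms + config$stimulus_duration_ms + iti
  first_onset <- cumsum(c(0, pair_period))
  events$onset_ms <- as.vector(rbind(first_onset,
                                     first_onset + config$soa_within_pair_ms))
  events
}

#' Validate an event schedule against the paradigm invariants
#'
#' Checks structural invariants (strictly increasing onsets, S in first
#' position, within-pair onset asynchrony, inter-pair jitter on the configured
#' grid, `global_context` defined exactly on second stimuli of S-T pairs),
#' compositional exactness against the configuration, the minimum-separation
#' constraint between S-T pairs, and homogeneity of each S-T pair's context
#' run.
#'
#' @param schedule An `lg_schedule` (or compatible tibble).
#' @param config The paradigm configuration; defaults to the one attached to
#'   the schedule.
#' @return A tibble of violations (`rule`, `pair_index`, `detail`); zero rows
#'   means the schedule is valid.
#' @export
validate_schedule <- function(schedule, config = attr(schedule, "config")) {
  bad <- list()
  note <- function(rule, pair_index, detail) {
    bad[[length(bad) + 1]] <<- tibble(rule = rule,
                                      pair_index = as.integer(pair_index),
                                      detail = detail)
  }

  if (any(diff(schedule$onset_ms) <= 0)) {
    i <- which(diff(schedule$onset_ms) <= 0)[1]
    note("onsets_increasing", schedule$pair_index[i], "onsets not strictly increasing")
  }
  first <- schedule[schedule$position == "first", ]
  second <- schedule[schedule$position == "second", ]
  wrong_first <- first$pair_index[first$stimulus_code != "S"]
  for (p in wrong_first) note("first_stimulus_is_S", p, "first stimulus of pair is not S")

  if (!is.null(config)) {
    soa <- second$onset_ms - first$onset_ms
    off <- which(abs(soa - config$soa_within_pair_ms) > 1e-9)
    for (p in first$pair_index[off])
      note("within_pair_soa", p, sprintf("SOA != %g ms", config$soa_within_pair_ms))
    if (nrow(first) > 1) {
      gap <- first$onset_ms[-1] - (second$onset_ms[-nrow(second)] +
                                     config$stimulus_duration_ms)
      grid <- seq(config$iti_min_ms, config$iti_max_ms, by = config$iti_step_ms)
      offgrid <- which(!vapply(gap, function(g) any(abs(g - grid) < 1e-9), TRUE))
      for (p in first$pair_index[offgrid + 1])
        note("inter_pair_jitter_grid", p, "inter-pair interval off the jitter grid")
    }
    an <- first[first$analyzed, ]
    cnt <- c(SS = sum(an$pair_type == "SS"), SF = sum(an$pair_type == "SF"),
             ST = sum(an$pair_type == "ST"))
    want <- c(SS = config$n_ss, SF = config$n_sf, ST = config$n_st)
    for (k in names(cnt)) if (cnt[[k]] != want[[k]])
      note("composition_exact", NA, sprintf("%s pairs: %d generated vs %d configured",
                                            k, cnt[[k]], want[[k]]))
    ctx <- second$global_context[second$pair_type == "ST" & second$analyzed]
    if (sum(ctx == "SS", na.rm = TRUE) != config$n_st_context_ss ||
        sum(ctx == "SF", na.rm = TRUE) != config$n_st_context_sf)
      note("context_counts", NA, "S-T context counts do not match configuration")
    m <- config$min_intervening_pairs
  } else m <- NULL

  st_pairs <- sort(unique(schedule$pair_index[schedule$pair_type == "ST"]))
  if (length(st_pairs) > 1 && !is.null(m)) {
    gaps <- diff(st_pairs) - 1L
    for (i in which(gaps < m))
      note("st_separation", st_pairs[i + 1],
           sprintf("only %d intervening pairs before this S-T pair", gaps[i]))
  }
  ptype <- first$pair_type[order(first$pair_index)]
  for (p in st_pairs) {
    if (p > 1 && ptype[p - 1] == "ST")
      note("context_preceding_not_st", p, "pair immediately before an S-T pair is S-T")
    ctx <- second$global_context[second$pair_index == p]
    if (!is.null(m) && !is.na(ctx) && m > 0) {
      run <- ptype[seq.int(max(1L, p - m), p - 1L)]
      want <- if (ctx == "SS") "SS" else "SF"
      if (p - m >= 1 && !all(run == want))
        note("context_run_homogeneous", p,
             sprintf("context run before S-T pair is not all %s", want))
    }
  }
  bad_ctx <- schedule$pair_index[
    (!is.na(schedule$global_context)) &
      !(schedule$pair_type == "ST" & schedule$position == "second")]
  for (p in unique(bad_ctx))
    note("context_only_on_st_second", p,
         "global_context set outside second stimulus of an S-T pair")

  if (length(bad) == 0)
    tibble(rule = character(), pair_index = integer(), detail = character())
  else bind_rows(bad)
}

#' Write / read a BIDS-style events table
#'
#' Columns follow BIDS events conventions: `onset` and `duration` in seconds,
#' `trial_type` (stimulus code), plus the paradigm columns `pair_index`,
#' `position`, `pair_type`, `global_context`, `analyzed`.
#'
#' @param schedule An `lg_schedule`.
#' @param path Output TSV path.
#' @param stimulus_duration_ms Stimulus duration used for the `duration`
#'   column; defaults to the attached configuration's value.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(schedule, path,
                             stimulus_duration_ms =
                               attr(schedule, "config")$stimulus_duration_ms %||% 200) {
  out <- tibble(
    onset = schedule$onset_ms / 1000,
    duration = stimulus_duration_ms / 1000,
    trial_type = schedule$stimulus_code,
    pair_index = schedule$pair_index,
    position = schedule$position,
    pair_type = schedule$pair_type,
    global_context = ifelse(is.na(schedule$global_context), "n/a",
                            schedule$global_context),
    analyzed = schedule$analyzed
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE, na = c("", "n/a"))
  out <- tibble(
    onset_ms = ev$onset * 1000,
    stimulus_code = ev$trial_type,
    pair_index = as.integer(ev$pair_index),
    position = ev$position,
    pair_type = ev$pair_type,
    global_context = as.character(ev$global_context),
    analyzed = as.logical(ev$analyzed)
  )
  class(out) <- c("lg_schedule", class(out))
  out
}
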