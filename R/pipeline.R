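#' Run the full infodemic-monitoring pipeline
#'
#' Composes the package's stages end to end: scores an annotation table on
#' the I-scale, joins the scores to keyword-level APC estimates and
#' aggregates them by severity, ranks the top keywords, computes hashtag
#' shares, correlates country-level search interest with incidence, and
#' writes one deterministic JSON report plus per-stage CSVs. Identical
#' inputs and seed produce a byte-identical report.
#'
#' @param config a named list (or path to a JSON file holding one) with
#'   entries:
#'   \describe{
#'     \item{annotations}{path to the annotation CSV (required).}
#'     \item{apc_table}{path to a keyword APC CSV
#'       (\code{keyword,total\[,ci_low,ci_high\]}); either this or
#'       \code{series} is required for the trends stage.}
#'     \item{series}{path to a series CSV (\code{keyword,geo,date,value});
#'       APC is computed per keyword when \code{apc_table} is absent.}
#'     \item{series_normalized}{logical, default TRUE.}
#'     \item{events}{optional path to an event-log CSV.}
#'     \item{hashtags}{optional path to a hashtag-count CSV.}
#'     \item{combined_tags}{optional character vector of tags whose
#'       combined share is reported.}
#'     \item{panel}{optional path to a country-panel CSV.}
#'     \item{window_days, confidence_level, spike_threshold,
#'       tolerance_days, share_method, ci_method, top_n, seed}{tuning
#'       parameters; defaults 7, 0.95, 50, 0, "sum_of_rounded",
#'       "variance", 10, 20200220.}
#'     \item{output_dir}{directory for outputs (required).}
#'   }
#' @return (invisibly) the report list; side effects are the files in
#'   \code{output_dir} (\code{scored_monikers.csv}, \code{apc_table.csv},
#'   \code{hashtag_shares.csv}, \code{report.json}). On any stage failure
#'   the partial outputs are removed and the error names the stage.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(list(
    window_days = 7, confidence_level = 0.95, spike_threshold = 50,
    tolerance_days = 0, share_method = "sum_of_rounded",
    ci_method = "variance", top_n = 10, seed = 20200220,
    series_normalized = TRUE), config)
  if (is.null(cfg$annotations))
    stage_error("config", "annotations path is required")
  if (is.null(cfg$output_dir))
    stage_error("config", "output_dir is required")
  stopifnot(cfg$window_days >= 1, cfg$confidence_level > 0,
            cfg$confidence_level < 1, cfg$spike_threshold > 0,
            cfg$spike_threshold <= 100, cfg$tolerance_days >= 0)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  log_stage <- function(stage, msg)
    message(sprintf("[%s] %s", stage, msg))

  # -- iscale ---------------------------------------------------------
  ann <- read_annotations(cfg$annotations)
  scored <- tryCatch(iscale(ann),
                     error = function(e) stage_error("iscale",
                                                     conditionMessage(e)))
  log_stage("iscale", sprintf("scored %d monikers", nrow(scored)))
  f <- file.path(cfg$output_dir, "scored_monikers.csv")
  write_csv_utf8(scored[c("moniker", "score", "severity")], f)
  written <- c(written, f)

  # -- trends ---------------------------------------------------------
  estimates <- NULL
  spikes_out <- NULL
  breakouts <- NULL
  if (!is.null(cfg$apc_table)) {
    estimates <- read_apc_table(cfg$apc_table)
  } else if (!is.null(cfg$series)) {
    series <- read_series(cfg$series, normalized = cfg$series_normalized)
    kw <- vapply(series, attr, character(1), "keyword")
    estimates <- do.call(rbind, lapply(unique(kw), function(k) {
      pk <- do.call(rbind, lapply(series[kw == k], extract_peaks,
                                  window_days = cfg$window_days))
      e <- apc(pk, level = cfg$confidence_level, keyword = k)
      data.frame(keyword = k, total = e$total, ci_low = e$ci_low,
                 ci_high = e$ci_high, n_obs = e$n_obs)
    }))
    spikes_out <- lapply(series, detect_spikes,
                         threshold = cfg$spike_threshold)
    breakouts <- lapply(series, detect_breakout)
  } else {
    stage_error("trends", "either apc_table or series input is required")
  }
  log_stage("trends", sprintf("%d keyword APC estimates (window %d days)",
                              nrow(estimates), cfg$window_days))
  f <- file.path(cfg$output_dir, "apc_table.csv")
  write_csv_utf8(estimates, f)
  written <- c(written, f)

  sev <- tryCatch(
    aggregate_by_severity(estimates, scored, ci_method = cfg$ci_method,
                          level = cfg$confidence_level),
    error = function(e) stage_error("trends", conditionMessage(e)))
  top <- rank_by_apc(estimates, n = cfg$top_n)
  top_scores <- coef(scored)[match(tolower(top$keyword),
                                   tolower(scored$moniker))]

  alignment <- NULL
  if (!is.null(cfg$events) && !is.null(spikes_out)) {
    events <- read_events(cfg$events)
    alignment <- lapply(names(spikes_out), function(nm) {
      k <- attr(series[[nm]], "keyword")
      align_events(spikes_out[[nm]],
                   events[events$keyword == k, , drop = FALSE],
                   tolerance_days = cfg$tolerance_days)
    })
    names(alignment) <- names(spikes_out)
  }

  # -- hashtags -------------------------------------------------------
  hashtag_block <- NULL
  if (!is.null(cfg$hashtags)) {
    ht <- tryCatch(shares(read_hashtags(cfg$hashtags)),
                   error = function(e) stage_error("hashtags",
                                                   conditionMessage(e)))
    log_stage("hashtags", sprintf("%d tags, grand total %g", nrow(ht),
                                  attr(ht, "grand_total")))
    f <- file.path(cfg$output_dir, "hashtag_shares.csv")
    write_csv_utf8(as.data.frame(ht), f)
    written <- c(written, f)
    comb <- if (!is.null(cfg$combined_tags))
      combined_share(ht, cfg$combined_tags, method = cfg$share_method)
    hashtag_block <- list(table = ht, combined = comb,
                          groups = group_summary(ht))
  }

  # -- association ----------------------------------------------------
  assoc <- NULL
  if (!is.null(cfg$panel)) {
    panel <- read_panel(cfg$panel)
    assoc <- tryCatch(panel_pearson(panel),
                      error = function(e) stage_error("association",
                                                      conditionMessage(e)))
    log_stage("association", sprintf("n=%d countries, r=%.2f", assoc$n,
                                     assoc$r))
  }

  # -- report ---------------------------------------------------------
  report <- write_report(
    list(config = cfg, iscale = scored, severity = sev, top = top,
         top_scores = top_scores, hashtags = hashtag_block,
         association = assoc, alignment = alignment),
    path = file.path(cfg$output_dir, "report.json"))
  written <- c(written, file.path(cfg$output_dir, "report.json"))
  ok <- TRUE
  invisible(report)
}

#' Assemble and serialize the pipeline report
#'
#' Produces a JSON document with stable field ordering and explicit display
#' precision: shares as percentages with one decimal, correlation r with
#' two decimals, and full-precision values under \code{raw} keys. P-values
#' below 0.001 are displayed as \code{"<.001"}.
#'
#' @param results list with components \code{config}, \code{iscale},
#'   \code{severity}, \code{top}, \code{top_scores}, and optionally
#'   \code{hashtags}, \code{association}, \code{alignment} (as assembled by
#'   [run_pipeline()]).
#' @param path output path for the JSON file, or NULL to skip writing.
#' @return the report as a named list (invisibly when written to file).
#' @export
write_report <- function(results, path = NULL) {
  need <- c("config", "iscale", "severity", "top")
  miss <- setdiff(need, names(results)[!vapply(results, is.null,
                                               logical(1))])
  if (length(miss) > 0L)
    stop("missing report section(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cfg <- results$config
  sev <- results$severity
  rep_list <- list(
    parameters = list(
      window_days = cfg$window_days,
      confidence_level = cfg$confidence_level,
      spike_threshold = cfg$spike_threshold,
      tolerance_days = cfg$tolerance_days,
      share_method = cfg$share_method,
      ci_method = cfg$ci_method,
      seed = cfg$seed),
    iscale = list(
      n_monikers = nrow(results$iscale),
      severity_counts = as.list(table(results$iscale$severity)),
      scores = stats::setNames(as.list(results$iscale$score),
                               results$iscale$moniker)),
    severity_summary = lapply(seq_len(nrow(sev)), function(i) list(
      severity = sev$severity[i],
      total_apc = sev$total_apc[i],
      share_pct = round_half_up(100 * sev$share[i], 1),
      share_excl_not_infodemic_pct =
        if (is.na(sev$share_excl_not_infodemic[i])) NULL
        else round_half_up(100 * sev$share_excl_not_infodemic[i], 1),
      ci_low = sev$ci_low[i], ci_high = sev$ci_high[i],
      n_keywords = sev$n_keywords[i],
      raw = list(share = sev$share[i]))),
    top_keywords = lapply(seq_len(nrow(results$top)), function(i) list(
      rank = i, keyword = results$top$keyword[i],
      total_apc = results$top$total[i],
      iscale_score = if (is.null(results$top_scores)) NULL
                     else unname(results$top_scores[i]))))
  if (!is.null(results$hashtags)) {
    ht <- results$hashtags$table
    rep_list$hashtags <- list(
      grand_total = attr(ht, "grand_total"),
      shares = lapply(seq_len(nrow(ht)), function(i) list(
        tag = ht$tag[i], count = ht$count[i],
        share_pct = ht$display_share[i],
        raw = list(share = ht$exact_share[i]))),
      combined = results$hashtags$combined,
      groups = lapply(seq_len(nrow(results$hashtags$groups)), function(i)
        list(group = results$hashtags$groups$group[i],
             total = results$hashtags$groups$total[i],
             share_pct = round_half_up(
               100 * results$hashtags$groups$share[i], 1))))
  }
  if (!is.null(results$association)) {
    a <- results$association
    rep_list$association <- list(
      r = round_half_up(a$r, 2), n = a$n,
      t_stat = a$t_stat,
      p_display = if (a$p_value < 0.001) "<.001"
                  else sprintf("%.3f", a$p_value),
      raw = list(r = a$r, p_value = a$p_value))
  }
  if (!is.null(results$alignment)) {
    rep_list$event_alignment <- lapply(results$alignment, function(al) list(
      n_matched = nrow(al$matches),
      n_unmatched_spikes = nrow(al$unmatched_spikes),
      n_unmatched_events = nrow(al$unmatched_events),
      matches = if (nrow(al$matches) == 0L) list() else
        lapply(seq_len(nrow(al$matches)), function(i) list(
          spike_date = as.character(al$matches$spike_date[i]),
          spike_value = al$matches$spike_value[i],
          event_date = as.character(al$matches$event_date[i]),
          event_label = al$matches$event_label[i]))))
  }
  if (!is.null(path)) {
    jsonlite::write_json(rep_list, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    return(invisible(rep_list))
  }
  rep_list
}
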