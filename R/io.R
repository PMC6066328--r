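# File formats: one CSV per force curve (columns time_s, distance_nm,
# force_pN) plus a JSON sidecar per dataset mapping curve_id to metadata;
# an events table CSV; and JSON fit/binding reports. Units are fixed in the
# column names -- no unit inference.

CURVE_COLUMNS <- c("time_s", "distance_nm", "force_pN")

#' Write force curves to a directory
#'
#' One `<curve_id>.csv` per curve with columns `time_s, distance_nm, force_pN`
#' and a `curves.json` sidecar mapping each `curve_id` to
#' `{velocity_nm_s, spring_constant_pN_nm, condition}`.
#'
#' @param curves List of [force_curve()] objects.
#' @param dir Output directory (created if absent).
#' @param condition Condition label stored in the sidecar (recycled).
#' @return `dir`, invisibly.
#' @export
write_force_curves <- function(curves, dir, condition = "unlabelled") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  condition <- rep_len(condition, length(curves))
  meta <- list()
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    df <- data.frame(time_s = cv$time, distance_nm = cv$tip_sample_distance,
                     force_pN = cv$force)
    utils::write.csv(df, file.path(dir, paste0(cv$curve_id, ".csv")),
                     row.names = FALSE)
    meta[[cv$curve_id]] <- list(velocity_nm_s = cv$pulling_velocity,
                                spring_constant_pN_nm = cv$spring_constant,
                                condition = condition[i])
  }
  jsonlite::write_json(meta, file.path(dir, "curves.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read force curves from a directory
#'
#' Reads the `curves.json` sidecar and every referenced per-curve CSV,
#' validating columns, monotone time and positive spring constants.
#'
#' @param path Dataset directory written by [write_force_curves()].
#' @return List of [force_curve()] objects; each carries a `condition`
#'   attribute from the sidecar.
#' @export
read_force_curves <- function(path) {
  sidecar <- file.path(path, "curves.json")
  if (!file.exists(sidecar))
    abort_format(sprintf("no curves.json sidecar found in '%s'", path))
  meta <- jsonlite::read_json(sidecar)
  curves <- vector("list", length(meta))
  for (i in seq_along(meta)) {
    id <- names(meta)[i]
    f <- file.path(path, paste0(id, ".csv"))
    if (!file.exists(f)) abort_format(sprintf("missing curve file '%s'", f))
    df <- utils::read.csv(f)
    missing_cols <- setdiff(CURVE_COLUMNS, names(df))
    if (length(missing_cols))
      abort_format(sprintf("curve '%s' lacks required column(s): %s",
                           id, paste(missing_cols, collapse = ", ")))
    m <- meta[[i]]
    if (is.null(m$velocity_nm_s) || is.null(m$spring_constant_pN_nm))
      abort_format(sprintf("sidecar entry for '%s' lacks velocity or spring constant", id))
    if (m$spring_constant_pN_nm <= 0)
      abort_validation(sprintf("curve '%s': spring constant must be positive", id))
    if (any(diff(df$time_s) <= 0))
      abort_validation(sprintf("curve '%s': time_s must be strictly increasing", id))
    cv <- force_curve(id, df$time_s, df$distance_nm, df$force_pN,
                      m$velocity_nm_s, m$spring_constant_pN_nm)
    attr(cv, "condition") <- m$condition %||% NA_character_
    curves[[i]] <- cv
  }
  curves
}

#' Write / read a rupture-events table
#'
#' CSV with columns `curve_id, rupture_force_pN, lc_nm, loading_rate_pN_s,
#' accepted`.
#'
#' @param events Events data frame (internal column names).
#' @param path CSV path.
#' @return `path` invisibly; `read_events()` returns the data frame with
#'   internal column names.
#' @export
write_events <- function(events, path) {
  out <- data.frame(curve_id = events$curve_id,
                    rupture_force_pN = events$rupture_force,
                    lc_nm = events$contour_length,
                    loading_rate_pN_s = events$loading_rate,
                    accepted = events$accepted)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path)
  need <- c("curve_id", "rupture_force_pN", "lc_nm", "loading_rate_pN_s", "accepted")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    abort_format(sprintf("events file lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  data.frame(curve_id = df$curve_id, rupture_force = df$rupture_force_pN,
             contour_length = df$lc_nm, loading_rate = df$loading_rate_pN_s,
             accepted = as.logical(df$accepted))
}

#' Write a kinetics fit report as JSON
#'
#' Versioned JSON mirroring the fitted quantities: `k0_off`, `x_beta`, their
#' 95% CIs, the per-cluster table, stage counts and provenance.
#'
#' @param report A `dfs_report` from [run_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(report, path) {
  fit <- report$fit
  out <- list(schema_version = "1.0",
              k0_off = fit$k0_off, x_beta = fit$x_beta,
              ci95_k0_off = fit$ci95_k0_off, ci95_x_beta = fit$ci95_x_beta,
              B = fit$B, response = fit$response,
              clusters = cluster_stats(fit$cluster_set),
              lc_filter = list(mu = report$lc_filter$mu,
                               sigma = report$lc_filter$sigma),
              counts = report$counts,
              provenance = report$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write a binding report as JSON
#'
#' One entry per condition mirroring an adhesion-frequency bar plot:
#' condition label, `p`, `se`, `p_ns`, `se_ns` and the comparison verdict.
#'
#' @param conditions Named list; each element a list with `specific`
#'   ([binding_probability()]), `baseline` ([nonspecific_baseline()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_binding_report <- function(conditions, path) {
  rows <- lapply(names(conditions), function(nm) {
    cnd <- conditions[[nm]]
    cmp <- compare_binding(cnd$specific, cnd$baseline)
    list(condition = nm, n_trials = cnd$specific$n_trials,
         p = cnd$specific$p, se = cnd$specific$se,
         p_ns = cnd$baseline$p_ns, se_ns = cnd$baseline$se_ns,
         difference = cmp$difference, verdict = cmp$verdict)
  })
  jsonlite::write_json(list(schema_version = "1.0", conditions = rows), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
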