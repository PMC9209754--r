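#' Arcsine square-root transformation of a percentage
#'
#' The variance-stabilising transform conventionally applied to percentage
#' traits before hypothesis testing: `asin(sqrt(p/100))`, in radians.
#' Strictly monotone on `[0, 100]`, mapping 0 to 0 and 100 to `pi/2`.
#'
#' @param p numeric vector of percentages in `[0, 100]`.
#' @return transformed values in radians.
#' @seealso [inv_arcsine_sqrt()]
#' @export
arcsine_sqrt <- function(p) {
  if (any(is.na(p))) stop_("NA in percentage input")
  if (any(p < 0 | p > 100)) stop_("percentages must lie in [0, 100]")
  asin(sqrt(p / 100))
}

#' Inverse arcsine square-root transformation
#'
#' @param x numeric vector in radians, in `[0, pi/2]`.
#' @return percentages in `[0, 100]`.
#' @export
inv_arcsine_sqrt <- function(x) {
  if (any(x < 0 | x > pi / 2 + 1e-12)) stop_("values must lie in [0, pi/2]")
  100 * sin(pmin(x, pi / 2))^2
}

#' Validate long-format phenotype records
#'
#' @param records data frame with columns `line_id`, `season_id`, `ser`
#'   (percentage in `[0, 100]`) and optionally `replicate`. `(line_id,
#'   season_id)` pairs may repeat only when `replicate` distinguishes them.
#' @return the validated data frame (invisibly usable downstream).
#' @export
phenotype_records <- function(records) {
  records <- as.data.frame(records)
  need <- c("line_id", "season_id", "ser")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop_("phenotype records missing column(s): ",
                          paste(miss, collapse = ", "))
  if (any(is.na(records$ser)) || any(records$ser < 0 | records$ser > 100))
    stop_("`ser` must lie in [0, 100]")
  key <- paste(records$line_id, records$season_id,
               if ("replicate" %in% names(records)) records$replicate else "")
  if (anyDuplicated(key))
    stop_("duplicate (line_id, season_id) records without a replicate index")
  records
}

#' Read long-format phenotype records from CSV
#'
#' Columns: `line_id`, `season_id`, optional `replicate`, and `ser` (or
#' `ser_percent`).
#'
#' @param path file path.
#' @return validated phenotype records data frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop_("phenotype file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if ("ser_percent" %in% names(df) && !"ser" %in% names(df))
    names(df)[names(df) == "ser_percent"] <- "ser"
  phenotype_records(df)
}

#' Summarise a trait by line or pyramid group
#'
#' The replication unit is the cropping season: plant-level replicates within
#' a season are averaged to one season value first, line summaries are the
#' mean and standard error over season values, and group summaries average
#' line means unweighted with the SE taken across lines. When the
#' arcsine-square-root scale is requested the transform is applied to the
#' raw observations before any aggregation.
#'
#' @param records phenotype records (see [phenotype_records()]).
#' @param panel a [genotype_panel()]; every `line_id` in `records` must be a
#'   panel line.
#' @param by `"line"` or `"group"`.
#' @param scale `"raw_percent"` or `"arcsine_sqrt"`.
#' @return a `trait_summary` data frame: `subject`, `mean`, `se`, `n`,
#'   `scale`. `se` is `NA` when `n == 1`.
#' @export
summarize_trait <- function(records, panel,
                            by = c("line", "group"),
                            scale = c("raw_percent", "arcsine_sqrt")) {
  by <- match.arg(by)
  scale <- match.arg(scale)
  records <- phenotype_records(records)
  stopifnot(inherits(panel, "genotype_panel"))
  unknown <- setdiff(unique(records$line_id), panel$lines$line_id)
  if (length(unknown))
    stop_("phenotype records for unknown line(s): ",
          paste(unknown, collapse = ", "))
  val <- if (scale == "arcsine_sqrt") arcsine_sqrt(records$ser) else records$ser
  # season value = mean over within-season replicates
  season <- stats::aggregate(val,
    by = list(line_id = records$line_id, season_id = records$season_id),
    FUN = mean)
  names(season)[3L] <- "value"
  line_stats <- do.call(rbind, lapply(split(season$value, season$line_id),
    function(v) data.frame(mean = mean(v),
                           se = if (length(v) > 1L)
                             stats::sd(v) / sqrt(length(v)) else NA_real_,
                           n = length(v))))
  line_stats$subject <- rownames(line_stats)
  rownames(line_stats) <- NULL
  if (by == "line") {
    out <- line_stats[, c("subject", "mean", "se", "n")]
  } else {
    grp <- panel$lines$group[match(line_stats$subject, panel$lines$line_id)]
    out <- do.call(rbind, lapply(split(line_stats$mean, grp), function(m)
      data.frame(mean = mean(m),
                 se = if (length(m) > 1L)
                   stats::sd(m) / sqrt(length(m)) else NA_real_,
                 n = length(m))))
    out$subject <- rownames(out)
    rownames(out) <- NULL
    out <- out[, c("subject", "mean", "se", "n")]
  }
  out$scale <- scale
  ord <- order(out$subject)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trait_summary", "data.frame")
  out
}

#' Reconstruct a group mean from subgroup means
#'
#' Count-weighted mean `sum(n_k * m_k) / sum(n_k)`; the exact inverse of
#' splitting a group into subgroups, so the reconstruction reproduces the
#' direct group mean on any data.
#'
#' @param means numeric vector of subgroup means.
#' @param n integer vector of subgroup sizes (all `>= 1`).
#' @return the weighted mean.
#' @export
group_mean_from_subgroups <- function(means, n) {
  if (length(means) == 0L) stop_("no subgroups supplied")
  if (length(means) != length(n)) stop_("`means` and `n` lengths differ")
  if (any(n < 1)) stop_("subgroup sizes must be >= 1")
  sum(n * means) / sum(n)
}

#' Read pre-aggregated trait summaries
#'
#' CSV with columns `subject`, `mean`, `se`, `n`, `scale` (and optionally
#' `subject_type`). Used when only published group summaries, not raw
#' per-line records, are available.
#'
#' @param path file path.
#' @return `trait_summary` data frame.
#' @export
read_trait_summaries <- function(path) {
  if (!file.exists(path)) stop_("summary file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject", "mean", "n")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_("summary file missing column(s): ",
                          paste(miss, collapse = ", "))
  if (!"se" %in% names(df)) df$se <- NA_real_
  if (!"scale" %in% names(df)) df$scale <- "raw_percent"
  class(df) <- c("trait_summary", "data.frame")
  df
}
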