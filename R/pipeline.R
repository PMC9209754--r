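#' Append one single-QTL line per locus to a panel
#'
#' Adds synthetic SSSL rows (`SSSL-<locus>`) carrying exactly one segment
#' each, so that estimators needing per-locus reference lines can run on
#' panels that enumerate only pyramids.
#'
#' @param panel a [genotype_panel()].
#' @return augmented [genotype_panel()].
#' @export
augment_with_ssls <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  loci <- colnames(panel$presence)
  new_ids <- paste0("SSSL-", loci)
  new_ids <- setdiff(new_ids, rownames(panel$presence))
  add <- matrix(FALSE, length(new_ids), length(loci),
                dimnames = list(new_ids, loci))
  for (id in new_ids) add[id, sub("^SSSL-", "", id)] <- TRUE
  genotype_panel(rbind(panel$presence, add),
                 control = panel$lines$line_id[panel$lines$is_control],
                 loci = panel$loci)
}

# Polynomial rolling hash of a string; stamps outputs with a config
# fingerprint (provenance only, no cryptographic claim).
#' @noRd
config_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @noRd
write_report <- function(df, path, config_string = "") {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("# qtlpyramid ",
           as.character(utils::packageVersion("qtlpyramid"))),
    paste0("# config ", config_hash(config_string))), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Estimate effects and epistasis from input files
#'
#' Runs the full estimation stage and writes CSV reports. Two input modes:
#'
#' * **summaries** (`summary_file` given): group-level trait summaries plus
#'   the genotype matrix and known single-QTL effects; produces
#'   `single_effects.csv`, `donor_effects.csv` and `group_effects.csv`
#'   (combination effects, group epistasis, per-QTL epistasis and epistasis
#'   fractions). This is the only mode possible when per-line raw data are
#'   not deposited.
#' * **records** (`phenotype_file` given): long-format per-season records;
#'   additionally produces `line_epistasis.csv` (per-line estimates with
#'   season-blocked t-tests) and `group_letters.csv` (Dunnett-adjusted
#'   p-values vs the control and Duncan significance letters across
#'   groups, on the test scale).
#'
#' @param genotype_file genotype table path (see [read_genotype_table()]).
#' @param metadata_file QTL metadata path; needed in summary mode (source
#'   of the known effects) and optional in records mode.
#' @param out_dir output directory (created if missing).
#' @param summary_file group-summary CSV (see [read_trait_summaries()]).
#' @param phenotype_file long-format phenotype CSV.
#' @param control control line id / summary subject.
#' @param test_scale scale for hypothesis tests.
#' @param alpha significance levels for the letter display.
#' @return invisible list of the computed tables.
#' @export
run_estimate <- function(genotype_file, metadata_file = NULL, out_dir,
                         summary_file = NULL, phenotype_file = NULL,
                         control = "HJX74",
                         test_scale = c("arcsine_sqrt", "raw_percent"),
                         alpha = c(0.05, 0.01)) {
  test_scale <- match.arg(test_scale)
  if (is.null(summary_file) && is.null(phenotype_file))
    stop_("need `summary_file` (group-summary mode) or `phenotype_file`")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  md <- if (!is.null(metadata_file)) read_qtl_metadata(metadata_file)
  panel <- read_genotype_table(genotype_file, control = control, loci = md)
  cfg <- paste(genotype_file, metadata_file, summary_file, phenotype_file,
               control, test_scale, paste(alpha, collapse = ","))
  out <- list()

  if (!is.null(summary_file)) {
    if (is.null(md)) stop_("summary mode needs `metadata_file` with known effects")
    eff <- additive_effects_from_metadata(md)
    summ <- read_trait_summaries(summary_file)
    cls <- classify_effect_levels(eff, k = 3L)
    single <- merge(cls$assignment,
                    md[, c("name", "donor_species")],
                    by.x = "locus", by.y = "name", sort = TRUE)
    out$single_effects <- single
    out$donor_effects <- aggregate_by_donor(eff, md)
    out$group_effects <- group_epistasis_from_summaries(
      panel, summ, eff, control_subject = control)
    write_report(single, file.path(out_dir, "single_effects.csv"), cfg)
    write_report(out$donor_effects,
                 file.path(out_dir, "donor_effects.csv"), cfg)
    write_report(out$group_effects,
                 file.path(out_dir, "group_effects.csv"), cfg)
  }

  if (!is.null(phenotype_file)) {
    rec <- read_phenotypes(phenotype_file)
    est <- estimate_epistasis(panel, rec, control = control,
                              test_scale = test_scale)
    out$line_epistasis <- est
    write_report(est, file.path(out_dir, "line_epistasis.csv"), cfg)
    out$group_letters <- group_letter_report(panel, rec, control,
                                             test_scale, alpha)
    write_report(out$group_letters,
                 file.path(out_dir, "group_letters.csv"), cfg)
  }
  invisible(out)
}

# Group mean/SE table with Dunnett-adjusted p vs control and Duncan letters.
# Replicates within a group are the line means (season-averaged); the
# control contributes its season values so it has replication too.
#' @noRd
group_letter_report <- function(panel, records, control, test_scale, alpha) {
  scale <- if (test_scale == "arcsine_sqrt") "arcsine_sqrt" else "raw_percent"
  ls_ <- summarize_trait(records, panel, by = "line", scale = scale)
  grp <- panel$lines$group[match(ls_$subject, panel$lines$line_id)]
  groups <- split(ls_$mean, grp)
  v <- if (scale == "arcsine_sqrt") arcsine_sqrt(records$ser) else records$ser
  ctl_season <- stats::aggregate(
    list(value = v[records$line_id == control]),
    by = list(season = records$season_id[records$line_id == control]),
    FUN = mean)$value
  groups[["control"]] <- ctl_season
  ord <- c(setdiff(names(groups), "control"), "control")
  groups <- groups[ord]
  ok <- vapply(groups, length, 1L) >= 2L
  dn <- dunnett_test(groups[ok & names(groups) != "control"], ctl_season)
  res <- data.frame(group = names(groups),
                    mean = vapply(groups, mean, 0),
                    se = vapply(groups, function(x)
                      stats::sd(x) / sqrt(length(x)), 0),
                    n = vapply(groups, length, 1L), row.names = NULL)
  res$p_dunnett <- dn$p_adj[match(res$group, dn$group)]
  for (a in alpha) {
    mr <- duncan_mrt(groups[ok], alpha = a)
    res[[paste0("letters_", a)]] <-
      mr$means$letters[match(res$group, mr$means$group)]
  }
  res
}

#' Simulate a pyramiding study to files
#'
#' Generates a genotype panel and multi-season phenotypes under a known
#' architecture and writes `genotypes.csv`, `phenotypes.csv` and the
#' configuration (`config.yml`). Deterministic given the config seed.
#'
#' @param out_dir output directory.
#' @param config an [architecture_config()].
#' @param design,k_loci,lines_per_group passed to [generate_panel()].
#' @param with_ssls also include one single-QTL line per locus when the
#'   design does not already (study preset).
#' @return invisible list with `panel` and `records`.
#' @export
run_simulate <- function(out_dir, config = architecture_config(),
                         design = "study_preset", k_loci = 11L,
                         lines_per_group = 2L, with_ssls = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- generate_panel(config, design = design, k_loci = k_loci,
                          lines_per_group = lines_per_group)
  if (with_ssls && design == "study_preset")
    panel <- augment_with_ssls(panel)
  rec <- generate_phenotypes(panel, config)
  write_genotype_table(panel, file.path(out_dir, "genotypes.csv"))
  utils::write.csv(rec, file.path(out_dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- config
  cfg$additive <- as.list(cfg$additive)
  cfg$epistasis$pairs <- as.list(cfg$epistasis$pairs)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yml"))
  invisible(list(panel = panel, records = rec))
}

#' Read an architecture configuration from YAML
#'
#' @param path YAML file as written by [run_simulate()].
#' @return an [architecture_config()].
#' @export
read_architecture_config <- function(path) {
  y <- yaml::read_yaml(path)
  architecture_config(P0 = y$P0, additive = unlist(y$additive),
                      epistasis = c(list(model = y$epistasis$model),
                                    lapply(y$epistasis[setdiff(
                                      names(y$epistasis), "model")], unlist)),
                      noise_sd = y$noise_sd, seasons = y$seasons,
                      season_effects = unlist(y$season_effects),
                      seed = y$seed)
}

#' Focal-QTL contrast report
#'
#' Splits the 2- to 4-QTL (or requested) groups by a focal locus and writes
#' `focal_contrast.csv`. Takes either per-line estimates (records mode
#' output of [run_estimate()]) or published subgroup summaries.
#'
#' @param genotype_file genotype table path.
#' @param focal locus name.
#' @param out_dir output directory.
#' @param estimates per-line `epistasis_estimate` data frame, or path to a
#'   `line_epistasis.csv` written by [run_estimate()].
#' @param subgroup_summary_file CSV of subgroup summaries
#'   (`group,subgroup,mean,n`), for summary mode.
#' @param metadata_file QTL metadata path (needed in summary mode).
#' @param P0 control mean for summary mode.
#' @param groups group labels to contrast.
#' @return invisible `focal_contrast` data frame.
#' @export
run_focal <- function(genotype_file, focal, out_dir, estimates = NULL,
                      subgroup_summary_file = NULL, metadata_file = NULL,
                      P0 = NULL, groups = c("2QL", "3QL", "4QL")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  md <- if (!is.null(metadata_file)) read_qtl_metadata(metadata_file)
  panel <- read_genotype_table(genotype_file, loci = md)
  if (is.null(estimates) && is.null(subgroup_summary_file))
    stop_("need `estimates` or `subgroup_summary_file`")
  if (!is.null(estimates)) {
    if (is.character(estimates))
      estimates <- utils::read.csv(estimates, comment.char = "#")
    ct <- focal_contrast(panel, estimates, focal, groups = groups)
  } else {
    if (is.null(md)) stop_("summary mode needs `metadata_file`")
    if (is.null(P0)) stop_("summary mode needs the control mean `P0`")
    eff <- additive_effects_from_metadata(md)
    ss <- utils::read.csv(subgroup_summary_file, stringsAsFactors = FALSE)
    ct <- focal_contrast_from_summaries(panel, ss[ss$group %in% groups, ],
                                        eff, focal, P0 = P0)
  }
  write_report(ct, file.path(out_dir, "focal_contrast.csv"),
               paste(genotype_file, focal))
  invisible(ct)
}

#' Batch simulation with estimator round trips
#'
#' Repeats phenotype generation over `n_panels` independent seeds on one
#' panel, re-estimates the single-QTL effects from the simulated SSSL and
#' control records, and summarises recovery per panel. Used to study
#' estimator bias and the monotonicity of group means under study-like
#' architectures.
#'
#' @param n_panels number of simulated panels.
#' @param config an [architecture_config()]; panel `p` uses seed
#'   `config$seed + p`.
#' @param panel panel to simulate on; default: the published panel
#'   augmented with per-locus SSSLs.
#' @return data frame per panel: `panel`, `mean_recovered_effect`,
#'   `mean_true_effect`, `bias` (recovered minus true grand mean),
#'   `mean_abs_error`, `groups_monotone` (group-mean trait rises with QTL
#'   count).
#' @export
simulate_batch <- function(n_panels, config = architecture_config(),
                           panel = augment_with_ssls(ser_study_panel())) {
  ctl <- panel$lines$line_id[panel$lines$is_control][1L]
  loci <- colnames(panel$presence)
  one <- panel$lines$line_id[!panel$lines$is_control &
                               panel$lines$qtl_count == 1L]
  loci1 <- vapply(one, function(id) loci[panel$presence[id, ]], "")
  truth <- config$additive[loci1]
  rows <- lapply(seq_len(n_panels), function(p) {
    cfg <- config
    cfg$seed <- config$seed + p
    rec <- suppressMessages(generate_phenotypes(panel, cfg))
    ls_ <- summarize_trait(rec, panel, by = "line")
    m <- stats::setNames(ls_$mean, ls_$subject)
    rec_eff <- m[one] - m[ctl]
    gs <- summarize_trait(rec, panel, by = "group")
    glab <- paste0(1:6, "QL")
    gm <- gs$mean[match(glab, gs$subject)]
    gm <- gm[!is.na(gm)]
    data.frame(panel = p,
               mean_recovered_effect = mean(rec_eff),
               mean_true_effect = mean(truth),
               bias = mean(rec_eff) - mean(truth),
               mean_abs_error = mean(abs(rec_eff - truth)),
               groups_monotone = !is.unsorted(gm, strictly = TRUE))
  })
  do.call(rbind, rows)
}
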