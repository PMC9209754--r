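#' Synthetic trait architecture configuration
#'
#' Describes a known additive/epistatic architecture for generating
#' multi-season percentage phenotypes. Defaults emulate the rice SER study
#' design: control baseline 29.2%, single-QTL additive effects of 13-27
#' percentage points, diminishing-returns (negative) epistasis growing with
#' QTL count, season-level noise of 3 percentage points, three cropping
#' seasons.
#'
#' @param P0 baseline (control) trait value, percent.
#' @param additive named numeric vector locus -> additive effect (percentage
#'   points). Default: the packaged reconstructed effects
#'   ([ser_study_effects()]).
#' @param epistasis one of `list(model = "none")`, `list(model = "pairwise",
#'   pairs = c("A:B" = -5, ...))`, or `list(model = "diminishing", c = 3.2)`
#'   where each co-resident QTL pair contributes `-c` so a line with `n`
#'   QTLs receives `-c * n * (n - 1) / 2` and the per-QTL epistasis
#'   `-c * (n - 1) / 2` grows in magnitude with `n`.
#' @param noise_sd standard deviation of the season-level noise, percentage
#'   points (`>= 0`).
#' @param seasons number of cropping seasons.
#' @param season_effects additive season offsets, recycled to `seasons`
#'   (default 0).
#' @param seed integer seed; fully determines the generated phenotypes.
#' @return object of class `architecture_config`.
#' @export
architecture_config <- function(P0 = 29.2, additive = ser_study_effects(),
                                epistasis = list(model = "diminishing", c = 3.2),
                                noise_sd = 3, seasons = 3L,
                                season_effects = 0, seed = 1L) {
  if (is.null(names(additive)) || !is.numeric(additive))
    stop_("`additive` must be a named numeric vector")
  if (noise_sd < 0) stop_("`noise_sd` must be non-negative")
  if (seasons < 1L) stop_("need at least one season")
  model <- match.arg(epistasis$model, c("none", "pairwise", "diminishing"))
  if (model == "pairwise" &&
      (is.null(epistasis$pairs) || is.null(names(epistasis$pairs))))
    stop_("pairwise model needs a named `pairs` vector (\"locusA:locusB\")")
  if (model == "diminishing" && is.null(epistasis$c))
    stop_("diminishing model needs a per-pair shrinkage `c`")
  structure(list(P0 = P0, additive = additive,
                 epistasis = c(list(model = model),
                               epistasis[setdiff(names(epistasis), "model")]),
                 noise_sd = noise_sd, seasons = as.integer(seasons),
                 season_effects = rep_len(season_effects, seasons),
                 seed = as.integer(seed)),
            class = "architecture_config")
}

#' Generate a genotype panel
#'
#' `design = "study_preset"` returns the packaged 11-locus, 31-line panel
#' (deterministic; the seed is ignored). `design = "random"` builds a panel
#' with `k_loci` synthetic loci, one single-QTL line per locus (the SSSLs)
#' and `lines_per_group` pyramiding lines for each QTL count from 2 up to
#' `min(6, k_loci)`, with loci drawn uniformly without replacement.
#'
#' @param config an [architecture_config()] (supplies the seed for the
#'   random design); may be `NULL` for the study preset.
#' @param design `"study_preset"` or `"random"`.
#' @param k_loci,lines_per_group random-design dimensions.
#' @param max_qtl largest pyramid size for the random design.
#' @return a [genotype_panel()] with control line `"HJX74"`.
#' @export
generate_panel <- function(config = NULL,
                           design = c("study_preset", "random"),
                           k_loci = 11L, lines_per_group = 2L,
                           max_qtl = 6L) {
  design <- match.arg(design)
  if (design == "study_preset") return(ser_study_panel())
  if (k_loci < 2L) stop_("random design needs at least 2 loci")
  top <- min(max_qtl, k_loci)
  if (top < 2L) stop_("infeasible design: cannot draw 2 loci from ", k_loci)
  seed <- if (!is.null(config)) config$seed else 1L
  suffix <- c("sat", "gla", "glu")
  loci <- sprintf("qSYN%02d-%s", seq_len(k_loci),
                  suffix[(seq_len(k_loci) - 1L) %% 3L + 1L])
  withr_seed(seed, {
    rows <- list()
    for (l in loci) {  # one SSSL per locus
      v <- stats::setNames(rep(FALSE, k_loci), loci); v[l] <- TRUE
      rows[[paste0("SSSL-", l)]] <- v
    }
    for (n in 2:top) for (r in seq_len(lines_per_group)) {
      v <- stats::setNames(rep(FALSE, k_loci), loci)
      v[sample(loci, n)] <- TRUE
      rows[[sprintf("%dQL-%d", n, r)]] <- v
    }
    pres <- do.call(rbind, rows)
  })
  genotype_panel(pres, control = "HJX74", max_qtl = max_qtl)
}

#' Expected (noise-free) genetic values of panel lines
#'
#' Baseline plus additive effects plus the architecture's epistatic
#' deviation, before noise and before clipping to `[0, 100]`.
#'
#' @param panel a [genotype_panel()].
#' @param config an [architecture_config()] whose `additive` covers every
#'   panel locus.
#' @return named numeric vector, one value per panel line.
#' @export
genetic_value <- function(panel, config) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(config, "architecture_config"))
  loci <- colnames(panel$presence)
  miss <- setdiff(loci, names(config$additive))
  if (length(miss)) stop_("config lacks additive effect for: ",
                          paste(miss, collapse = ", "))
  a <- config$additive[loci]
  add <- as.numeric(panel$presence %*% a)
  epi <- vapply(seq_len(nrow(panel$presence)), function(r) {
    present <- loci[panel$presence[r, ]]
    n <- length(present)
    switch(config$epistasis$model,
      none = 0,
      diminishing = -config$epistasis$c * n * (n - 1) / 2,
      pairwise = {
        if (n < 2L) 0 else {
          prs <- utils::combn(sort(present), 2L)
          keys <- paste(prs[1L, ], prs[2L, ], sep = ":")
          sum(config$epistasis$pairs[keys], na.rm = TRUE)
        }
      })
  }, 0)
  stats::setNames(config$P0 + add + epi, rownames(panel$presence))
}

#' Generate multi-season percentage phenotypes
#'
#' For each line and season: `SER = clip(genetic value + season offset +
#' noise, 0, 100)` with `noise ~ Normal(0, noise_sd)` applied on the raw
#' percentage scale. The seed in `config` fully determines the output;
#' clipping events are counted in the `"clipped"` attribute and reported
#' with a message.
#'
#' @param panel a [genotype_panel()].
#' @param config an [architecture_config()].
#' @return phenotype records data frame (`line_id`, `season_id`, `ser`) with
#'   attribute `clipped` (number of clipped observations).
#' @export
generate_phenotypes <- function(panel, config) {
  g <- genetic_value(panel, config)
  seasons <- sprintf("S%02d", seq_len(config$seasons))
  df <- expand.grid(line_id = names(g), season_id = seasons,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[order(match(df$line_id, names(g)), df$season_id), ]
  rownames(df) <- NULL
  mu <- g[df$line_id] + config$season_effects[match(df$season_id, seasons)]
  withr_seed(config$seed, {
    eps <- if (config$noise_sd > 0)
      stats::rnorm(nrow(df), 0, config$noise_sd) else 0
  })
  raw <- mu + eps
  clipped <- sum(raw < 0 | raw > 100)
  if (clipped > 0)
    message(clipped, " observation(s) clipped to [0, 100]")
  df$ser <- pmin(100, pmax(0, unname(raw)))
  attr(df, "clipped") <- clipped
  phenotype_records(df)
  df
}
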