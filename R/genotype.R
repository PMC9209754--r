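#' Infer donor species from a QTL name suffix
#'
#' QTL names carry a three-letter suffix identifying the donor species of the
#' substitution segment, e.g. `qSER3a-sat` (*O. sativa*), `qSER8b-gla`
#' (*O. glaberrima*), `qSER5-glu` (*O. glumaepatula*).
#'
#' @param name character vector of QTL names.
#' @return character vector with values `"sativa"`, `"glaberrima"`,
#'   `"glumaepatula"` or `NA` when the suffix is absent or unknown.
#' @export
donor_from_name <- function(name) {
  suffix <- sub(".*-", "", name)
  map <- c(sat = "sativa", gla = "glaberrima", glu = "glumaepatula")
  out <- unname(map[suffix])
  out[!grepl("-", name)] <- NA_character_
  out
}

#' Construct a genotype panel
#'
#' A genotype panel holds the line-by-locus presence/absence matrix of donor
#' substitution segments, the per-line bookkeeping (QTL count, pyramid group)
#' and optional QTL metadata.
#'
#' @param presence logical matrix, rows = lines, columns = QTL loci; both
#'   dimensions must be named.
#' @param control character vector of control line ids (zero substitution
#'   segments, e.g. `"HJX74"`). Control rows may be absent from `presence`;
#'   they are then appended as all-`FALSE` rows.
#' @param loci optional data frame of QTL metadata with at least a `name`
#'   column; may carry `donor_species`, `linked_group`,
#'   `known_additive_effect`. Checked against the matrix columns.
#' @param max_qtl maximum QTL count accepted for a non-control line.
#' @return an object of class `genotype_panel`: a list with elements
#'   `presence` (logical matrix), `lines` (data frame: `line_id`,
#'   `is_control`, `qtl_count`, `group`) and `loci` (data frame).
#' @export
genotype_panel <- function(presence, control = character(), loci = NULL,
                           max_qtl = 6L) {
  if (!is.matrix(presence) || !is.logical(presence))
    stop_("`presence` must be a logical matrix")
  if (is.null(rownames(presence)) || is.null(colnames(presence)))
    stop_("`presence` must have line ids as rownames and locus names as colnames")
  if (anyDuplicated(rownames(presence)))
    stop_("duplicate line_id: ",
          paste(unique(rownames(presence)[duplicated(rownames(presence))]),
                collapse = ", "))
  if (anyDuplicated(colnames(presence)))
    stop_("duplicate locus names in panel")
  missing_ctrl <- setdiff(control, rownames(presence))
  if (length(missing_ctrl)) {
    pad <- matrix(FALSE, length(missing_ctrl), ncol(presence),
                  dimnames = list(missing_ctrl, colnames(presence)))
    presence <- rbind(pad, presence)
  }
  is_control <- rownames(presence) %in% control
  qtl_count <- as.integer(rowSums(presence))
  if (any(is_control & qtl_count > 0L))
    stop_("control line carries substitution segments: ",
          paste(rownames(presence)[is_control & qtl_count > 0L], collapse = ", "))
  bad <- !is_control & (qtl_count < 1L | qtl_count > max_qtl)
  if (any(bad))
    stop_("non-control lines must carry 1-", max_qtl, " QTLs; offending: ",
          paste(rownames(presence)[bad], collapse = ", "))
  if (is.null(loci)) {
    loci <- data.frame(name = colnames(presence),
                       donor_species = donor_from_name(colnames(presence)),
                       stringsAsFactors = FALSE)
  } else {
    loci <- as.data.frame(loci)
    if (!"name" %in% names(loci)) stop_("`loci` needs a `name` column")
    if (!setequal(loci$name, colnames(presence)))
      stop_("`loci` metadata does not match the panel's loci")
    loci <- loci[match(colnames(presence), loci$name), , drop = FALSE]
    rownames(loci) <- NULL
    if ("donor_species" %in% names(loci)) {
      inferred <- donor_from_name(loci$name)
      clash <- !is.na(inferred) & !is.na(loci$donor_species) &
        inferred != loci$donor_species
      if (any(clash))
        stop_("donor_species disagrees with name suffix for: ",
              paste(loci$name[clash], collapse = ", "))
    }
  }
  lines <- data.frame(
    line_id = rownames(presence),
    is_control = is_control,
    qtl_count = qtl_count,
    group = ifelse(is_control, "control", paste0(qtl_count, "QL")),
    stringsAsFactors = FALSE
  )
  rownames(lines) <- NULL
  structure(list(presence = presence, lines = lines, loci = loci),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  n_ctl <- sum(x$lines$is_control)
  cat("genotype_panel: ", ncol(x$presence), " loci, ",
      nrow(x$presence) - n_ctl, " lines",
      if (n_ctl) paste0(" + ", n_ctl, " control"), "\n", sep = "")
  tab <- table(x$lines$group[!x$lines$is_control])
  ord <- order(as.integer(sub("QL", "", names(tab))))
  cat("  groups:", paste0(names(tab)[ord], "=", tab[ord], collapse = ", "), "\n")
  invisible(x)
}

# Token sets accepted for presence/absence cells. Published tables print
# "+/-" with typographic dashes (en dash, minus sign); CSV exports vary.
.presence_tokens <- c("+", "1", "TRUE", "T", "true")
.absence_tokens  <- c("-", "−", "–", "0", "FALSE", "F", "false")

#' Read a line-by-QTL genotype table
#'
#' Expects a delimited file with a header row of locus names, a first column
#' of line ids and optionally a second column with a pyramid group label
#' (recomputed from the matrix and cross-checked when present). Cells are
#' presence/absence tokens; `+`/`-` (including typographic dashes), `1`/`0`
#' and `TRUE`/`FALSE` are accepted by default.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) picks `\t` or `,` from the
#'   header line.
#' @param control character vector of line ids treated as controls.
#' @param presence_tokens,absence_tokens tokens mapped to `TRUE`/`FALSE`.
#' @param loci optional QTL metadata data frame passed to [genotype_panel()].
#' @return a [genotype_panel()].
#' @export
read_genotype_table <- function(path, sep = NULL, control = "HJX74",
                                presence_tokens = .presence_tokens,
                                absence_tokens = .absence_tokens,
                                loci = NULL) {
  if (!file.exists(path)) stop_("genotype table not found: ", path)
  header <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", fill = FALSE,
                           fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) stop_("genotype table has no data rows: ", path)
  line_id <- trimws(raw[[1L]])
  if (anyDuplicated(line_id))
    stop_("duplicate line_id in ", path, ": ",
          paste(unique(line_id[duplicated(line_id)]), collapse = ", "))
  body <- raw[, -1L, drop = FALSE]
  group_given <- NULL
  if (ncol(body) && names(body)[1L] %in% c("group", "Group")) {
    group_given <- trimws(body[[1L]])
    body <- body[, -1L, drop = FALSE]
  }
  if (ncol(body) == 0L) stop_("genotype table has no locus columns: ", path)
  cells <- trimws(as.matrix(body))
  known <- matrix(cells %in% c(presence_tokens, absence_tokens),
                  nrow = nrow(cells))
  if (!all(known)) {
    idx <- which(!known, arr.ind = TRUE)[1L, ]
    stop_("unknown presence/absence token ", dQuote(cells[!known][1L]),
          " at row ", idx[1L], " (line ", line_id[idx[1L]], "), locus ",
          colnames(cells)[idx[2L]])
  }
  pres <- matrix(cells %in% presence_tokens, nrow = nrow(cells),
                 dimnames = list(line_id, colnames(cells)))
  panel <- genotype_panel(pres, control = intersect(control, line_id),
                          loci = loci)
  if (!is.null(group_given)) {
    derived <- panel$lines$group[match(line_id, panel$lines$line_id)]
    bad <- group_given != derived
    if (any(bad))
      stop_("group label disagrees with QTL count for: ",
            paste0(line_id[bad], " (given ", group_given[bad], ", derived ",
                   derived[bad], ")", collapse = ", "))
  }
  panel
}

#' Write a genotype panel back to a delimited table
#'
#' Inverse of [read_genotype_table()]: emits line id, derived group label and
#' one presence/absence column per locus, preserving locus order.
#'
#' @param panel a [genotype_panel()].
#' @param path output file path.
#' @param tokens length-2 character vector: presence and absence token.
#' @param sep field separator.
#' @param include_group write the derived group column.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(panel, path, tokens = c("+", "-"),
                                 sep = ",", include_group = TRUE) {
  mat <- ifelse(panel$presence, tokens[1L], tokens[2L])
  df <- data.frame(line_id = rownames(panel$presence),
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (include_group)
    df$group <- panel$lines$group[match(df$line_id, panel$lines$line_id)]
  df <- cbind(df, as.data.frame(mat, check.names = FALSE))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Partition non-control lines by pyramid group
#'
#' @param panel a [genotype_panel()].
#' @return named list, `1QL` ... `6QL` (only occupied groups), each a
#'   character vector of line ids in panel order.
#' @export
lines_by_group <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  ln <- panel$lines[!panel$lines$is_control, , drop = FALSE]
  if (nrow(ln) == 0L) return(structure(list(), names = character()))
  counts <- sort(unique(ln$qtl_count))
  out <- lapply(counts, function(n) ln$line_id[ln$qtl_count == n])
  names(out) <- paste0(counts, "QL")
  out
}

#' Split pyramid groups by presence of a focal locus
#'
#' Within each requested pyramid group, partitions the lines into those
#' carrying and those lacking the focal QTL.
#'
#' @param panel a [genotype_panel()].
#' @param focal locus name, e.g. `"qSER3a-sat"`.
#' @param groups character vector of group labels (default: all occupied
#'   groups).
#' @return named list per group with elements `with` and `without`
#'   (character vectors of line ids).
#' @export
split_by_focal_locus <- function(panel, focal, groups = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!focal %in% colnames(panel$presence))
    stop_("unknown locus: ", focal)
  by_grp <- lines_by_group(panel)
  groups <- groups %||% names(by_grp)
  missing <- setdiff(groups, names(by_grp))
  if (length(missing)) stop_("no lines in group(s): ",
                             paste(missing, collapse = ", "))
  out <- lapply(groups, function(g) {
    ids <- by_grp[[g]]
    has <- panel$presence[ids, focal]
    list(with = ids[has], without = ids[!has])
  })
  names(out) <- groups
  out
}

#' Read QTL metadata
#'
#' Tab-separated file with columns `name`, `donor_species`, and optionally
#' `linked_group` (loci co-resident on one substitution segment) and
#' `known_additive_effect` (percentage points).
#'
#' @param path file path.
#' @return data frame of metadata; donor suffixes are checked against
#'   `donor_species`.
#' @export
read_qtl_metadata <- function(path) {
  if (!file.exists(path)) stop_("QTL metadata not found: ", path)
  md <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (!all(c("name", "donor_species") %in% names(md)))
    stop_("metadata needs `name` and `donor_species` columns")
  inferred <- donor_from_name(md$name)
  clash <- !is.na(inferred) & inferred != md$donor_species
  if (any(clash))
    stop_("donor_species disagrees with name suffix for: ",
          paste(md$name[clash], collapse = ", "))
  md
}

#' Named vector of known single-QTL additive effects from metadata
#'
#' @param metadata data frame as returned by [read_qtl_metadata()].
#' @return named numeric vector (percentage points), `NA` dropped.
#' @export
additive_effects_from_metadata <- function(metadata) {
  if (!"known_additive_effect" %in% names(metadata))
    stop_("metadata has no `known_additive_effect` column")
  eff <- stats::setNames(as.numeric(metadata$known_additive_effect),
                         metadata$name)
  eff[!is.na(eff)]
}
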