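#' Compute sex-bias trait metrics from raw sex-specific records
#'
#' Converts raw per-species demographic records into the analysis metrics:
#' \describe{
#'   \item{asr, bsr}{proportion of males, `males / (males + females)`, from
#'     adult and birth counts (or given directly as proportions).}
#'   \item{jmb, amb}{log10 ratio of male to female annual juvenile / adult
#'     mortality rates; positive values mean higher male mortality.}
#'   \item{mat}{log10 ratio of male to female maturation age; positive values
#'     mean males mature later.}
#' }
#' When a species has several population records the species mean of each
#' metric is used. A female rate of zero makes the metric missing (with a
#' warning) rather than infinite; negative rates, counts, or ages are errors.
#'
#' @param raw A data.frame with column `species` and any of:
#'   `adult_males`/`adult_females` (counts) or `asr` (proportion),
#'   `birth_males`/`birth_females` or `bsr`,
#'   `juv_mort_male`/`juv_mort_female`, `ad_mort_male`/`ad_mort_female`,
#'   `mat_age_male`/`mat_age_female`, and optionally `gsd` (\"XY\"/\"ZW\").
#' @return A `TraitTable` data.frame with one row per species and columns
#'   `species`, `gsd`, `asr`, `bsr`, `jmb`, `amb`, `mat`.
#' @export
compute_bias_metrics <- function(raw) {
  stopifnot(is.data.frame(raw), "species" %in% names(raw))
  num_cols <- setdiff(names(raw), c("species", "gsd"))
  for (cc in num_cols) {
    v <- raw[[cc]]
    if (any(!is.na(v) & v < 0))
      stop("negative values in column '", cc, "'")
  }
  log_ratio <- function(m, f, what) {
    out <- rep(NA_real_, length(m))
    zero_f <- !is.na(f) & f == 0
    if (any(zero_f))
      warning("female ", what, " of zero for ",
              sum(zero_f), " record(s); metric set to missing")
    ok <- !is.na(m) & !is.na(f) & f > 0 & m > 0
    out[ok] <- log10(m[ok] / f[ok])
    out
  }
  prop <- function(m, f) {
    out <- rep(NA_real_, length(m))
    ok <- !is.na(m) & !is.na(f) & (m + f) > 0
    out[ok] <- m[ok] / (m[ok] + f[ok])
    out
  }
  n <- nrow(raw)
  get <- function(nm) if (nm %in% names(raw)) raw[[nm]] else rep(NA_real_, n)
  asr <- if ("asr" %in% names(raw)) raw$asr else prop(get("adult_males"), get("adult_females"))
  bsr <- if ("bsr" %in% names(raw)) raw$bsr else prop(get("birth_males"), get("birth_females"))
  rec <- data.frame(
    species = raw$species,
    asr = asr, bsr = bsr,
    jmb = log_ratio(get("juv_mort_male"), get("juv_mort_female"), "juvenile mortality"),
    amb = log_ratio(get("ad_mort_male"), get("ad_mort_female"), "adult mortality"),
    mat = log_ratio(get("mat_age_male"), get("mat_age_female"), "maturation age"),
    stringsAsFactors = FALSE
  )
  bad_prop <- c(rec$asr, rec$bsr)
  if (any(!is.na(bad_prop) & (bad_prop < 0 | bad_prop > 1)))
    stop("sex-ratio proportions outside [0, 1]")
  # species-level means over multiple population records
  agg <- stats::aggregate(rec[-1], by = list(species = rec$species),
                          FUN = function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  if ("gsd" %in% names(raw)) {
    g <- stats::aggregate(list(gsd = raw$gsd), by = list(species = raw$species),
                          FUN = function(v) {
                            u <- unique(v[!is.na(v)])
                            if (length(u) == 0L) NA_character_
                            else if (length(u) > 1L) stop("conflicting GSD for a species")
                            else u
                          })
    agg <- merge(agg, g, by = "species", sort = TRUE)
  } else agg$gsd <- NA_character_
  if (any(!is.na(agg$gsd) & !agg$gsd %in% c("XY", "ZW")))
    stop("gsd must be 'XY' or 'ZW'")
  agg[c("species", "gsd", "asr", "bsr", "jmb", "amb", "mat")]
}

#' Standardize a numeric vector to z-scores
#'
#' Centres to mean 0 and scales to SD 1 (sample SD, n - 1 denominator) over
#' the non-missing entries; missing values are preserved.
#'
#' @param values Numeric vector, possibly with `NA`.
#' @return z-scored vector of the same length.
#' @export
standardize <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values")
  s <- stats::sd(values[ok])
  if (!is.finite(s) || s == 0)
    stop("constant column cannot be standardized")
  out <- values
  out[ok] <- (values[ok] - mean(values[ok])) / s
  out
}

#' Add standardized copies of the continuous trait columns
#'
#' @param table A `TraitTable` data.frame.
#' @param variables Columns to standardize (default all continuous metrics
#'   present).
#' @return The table with `<var>_z` columns appended.
#' @export
standardize_traits <- function(table,
                               variables = intersect(c("asr", "bsr", "jmb", "amb", "mat"),
                                                     names(table))) {
  for (v in variables) table[[paste0(v, "_z")]] <- standardize(table[[v]])
  table
}

#' Flag high-leverage outliers within sex-determination groups
#'
#' A species is flagged when its value lies more than three standard
#' deviations from its group (XY or ZW) mean, each group assessed on its own
#' mean and SD. Groups with fewer than three members yield no flags (with a
#' warning).
#'
#' @param values Numeric vector (typically a standardized predictor).
#' @param groups Character/factor vector of group labels, same length.
#' @param threshold SD multiple beyond which a point is flagged (default 3).
#' @return Logical vector; `NA` values are never flagged.
#' @export
flag_outliers <- function(values, groups, threshold = 3) {
  stopifnot(length(values) == length(groups))
  flags <- rep(FALSE, length(values))
  for (g in unique(groups[!is.na(groups)])) {
    idx <- which(!is.na(values) & !is.na(groups) & groups == g)
    if (length(idx) < 3L) {
      warning("group '", g, "' has fewer than 3 members; no outliers flagged")
      next
    }
    m <- mean(values[idx]); s <- stats::sd(values[idx])
    if (s > 0) flags[idx] <- abs(values[idx] - m) / s > threshold
  }
  flags
}

#' Complete-case subset for a model, with matching tree
#'
#' Restricts a trait table to rows complete for the named variables, prunes
#' the tree to the matching tips, and (by default) recomputes standardized
#' columns on the subset so per-model coefficients keep their effect-size
#' interpretation.
#'
#' @param table A `TraitTable` data.frame with a `species` column.
#' @param variables Character vector of required columns.
#' @param tree A `"phylo"` object, or `NULL` to subset the table only.
#' @param restandardize Recompute `<var>_z` columns on the subset
#'   (default `TRUE`); set `FALSE` to keep full-table z-scores.
#' @return A list with `table`, `tree` (pruned or `NULL`), and `n`.
#' @export
model_subset <- function(table, variables, tree = NULL, restandardize = TRUE) {
  miss <- setdiff(variables, names(table))
  if (length(miss)) stop("unknown variables: ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(table[variables])
  tab <- table[keep, , drop = FALSE]
  if (!is.null(tree)) {
    common <- intersect(tab$species, tree$tip.label)
    if (length(common) == 0L) stop("no species shared between table and tree")
    tab <- tab[tab$species %in% common, , drop = FALSE]
    tree <- prune_to(tree, common)
  }
  if (nrow(tab) == 0L) stop("empty subset")
  if (restandardize) {
    cont <- intersect(variables, c("asr", "bsr", "jmb", "amb", "mat"))
    for (v in cont) tab[[paste0(v, "_z")]] <- standardize(tab[[v]])
  }
  list(table = tab, tree = tree, n = nrow(tab))
}

#' Read a trait CSV with optional column-name mapping
#'
#' @param path CSV path.
#' @param mapping Named character vector mapping file column names to the
#'   canonical names (`species`, `gsd`, `asr`, `bsr`, `jmb`, `amb`, `mat`),
#'   e.g. `c(Species = "species", ASR = "asr")`. Unmapped columns are kept
#'   as-is.
#' @return A data.frame.
#' @export
read_trait_csv <- function(path, mapping = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    hit <- names(tab) %in% names(mapping)
    names(tab)[hit] <- unname(mapping[names(tab)[hit]])
  }
  if (!"species" %in% names(tab)) stop("no 'species' column after mapping")
  if (anyDuplicated(tab$species)) stop("duplicate species rows")
  tab
}

#' Write the analysis-ready trait table
#'
#' @param table TraitTable data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
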