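# Raw count matrix -> per-sample averaged trait profiles: presence/absence
# conversion, composite-taxon averaging, cleaning filters, FLOWPER merging.

#' Read a taxa-by-samples count matrix
#'
#' The first column (`species.codes`) holds species codes; every remaining
#' column is one archaeobotanical sample, cells are seed counts (blank = 0).
#'
#' @param path CSV file path.
#' @return Numeric matrix, rows = taxa (codes, lowercased), columns = samples.
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L)
    stop("count CSV needs a `species.codes` column plus >= 1 sample column",
         call. = FALSE)
  codes <- tolower(as.character(df[[1L]]))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "numeric"
  m[is.na(m)] <- 0
  rownames(m) <- codes
  validate_counts(m)
  m
}

validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (taxa x samples)", call. = FALSE)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("counts must have at least one taxon and one sample", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry taxon codes as rownames and sample ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon codes in counts: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  if (any(counts < 0))
    stop("negative counts are not allowed", call. = FALSE)
  invisible(counts)
}

#' Convert counts to presence/absence
#'
#' Seed counts carry taphonomic noise, so community composition is compared on
#' presence/absence: any positive count becomes 1. Idempotent.
#'
#' @param counts Numeric taxa-by-samples matrix with non-negative entries.
#' @return Matrix of the same shape with values in \{0, 1\}.
#' @export
to_presence_absence <- function(counts) {
  validate_counts(counts)
  (counts > 0) * 1
}

#' Drop low-count samples, flag low-diversity ones
#'
#' Applies the minimum seed-count filter to raw (pre presence/absence) counts:
#' samples with fewer than `min_seeds` weed seeds in total are dropped
#' (boundary inclusive: exactly `min_seeds` is kept). Retained samples with
#' fewer than three taxa are flagged as low-diversity but NOT dropped, so the
#' analysis can be run both with and without them.
#'
#' @param counts Raw numeric taxa-by-samples matrix.
#' @param min_seeds Minimum total seed count per sample (default 10, a
#'   recommendation, not a hard rule).
#' @return List with `counts` (retained columns) and `report`, a list holding
#'   `dropped` (data frame of sample/total) and `low_diversity` (character
#'   vector of retained sample ids with < 3 taxa).
#' @export
clean_samples <- function(counts, min_seeds = 10) {
  validate_counts(counts)
  totals <- colSums(counts)
  keep <- totals >= min_seeds
  if (!any(keep))
    stop("all samples fall below min_seeds = ", min_seeds, call. = FALSE)
  kept <- counts[, keep, drop = FALSE]
  ntaxa <- colSums(kept > 0)
  report <- list(
    dropped = data.frame(sample = colnames(counts)[!keep],
                         total = unname(totals[!keep]),
                         stringsAsFactors = FALSE),
    low_diversity = colnames(kept)[ntaxa < 3L],
    min_seeds = min_seeds)
  list(counts = kept, report = report)
}

#' Average several species into a composite taxon
#'
#' Seeds identifiable only to a small set of candidate species are represented
#' by a composite pseudo-species whose trait values are the per-trait
#' arithmetic mean over the member species with non-missing values. A trait
#' missing in all members stays missing. `overrides` are applied last; an
#' explicit `NA` override blanks a trait, excluding the composite from any
#' calculation that uses it (the typical case is VEGPROP when the members'
#' propagation behaviour is uncertain). Averaging more than four species
#' triggers a caution, and the members' trait ranges are attached as the
#' `"member_range"` attribute so divergence can be eyeballed — divergence is
#' advisory, never blocking.
#'
#' @param db A [trait_db].
#' @param code New composite species code (must not collide with `db`).
#' @param members Character vector (length >= 2) of member species codes.
#' @param overrides Optional named list/vector of trait replacements
#'   (value or `NA`).
#' @return One-row data frame of averaged trait values for the composite.
#' @export
average_composite <- function(db, code, members, overrides = NULL) {
  stopifnot(inherits(db, "trait_db"))
  code <- tolower(code)
  members <- tolower(members)
  if (code %in% db$records$code)
    stop("composite code '", code, "' already exists in the trait database",
         call. = FALSE)
  if (length(members) < 2L)
    stop("a composite needs at least two member species", call. = FALSE)
  absent <- setdiff(members, db$records$code)
  if (length(absent))
    stop("composite members not in trait database: ",
         paste(absent, collapse = ", "), call. = FALSE)
  if (length(members) > 4L)
    warning("averaging more than four species (", length(members),
            ") for '", code, "'; composite trait values may be meaningless",
            call. = FALSE)
  rows <- db$records[match(members, db$records$code), , drop = FALSE]
  num_traits <- intersect(TRAIT_ORDER, names(rows))
  out <- data.frame(code = code, stringsAsFactors = FALSE)
  rng <- list()
  for (tr in num_traits) {
    v <- rows[[tr]]
    ok <- !is.na(v)
    out[[tr]] <- if (any(ok)) mean(v[ok]) else NA_real_
    rng[[tr]] <- if (any(ok)) range(v[ok]) else c(NA_real_, NA_real_)
  }
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), num_traits)
    if (length(unknown))
      stop("override names not traits: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    for (tr in names(overrides))
      out[[tr]] <- as.numeric(overrides[[tr]])
  }
  attr(out, "member_range") <- rng
  out
}

#' Read a composite-taxon specification CSV
#'
#' Columns: `composite_code,member1,member2,member3,member4` (blank member
#' cells ignored) plus optional override columns named after traits; an
#' override cell value of `NA` blanks that trait in the composite.
#'
#' @param path CSV path.
#' @param db A [trait_db] used to resolve member trait values.
#' @return Data frame of composite trait records (one row per composite),
#'   suitable for the `composites` argument of [organise()].
#' @export
read_composites_csv <- function(path, db) {
  # read everything as character: a blank override cell means "no override",
  # a literal NA cell means "blank this trait in the composite"
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character", na.strings = character())
  if (!"composite_code" %in% names(df))
    stop("composite CSV needs a `composite_code` column", call. = FALSE)
  member_cols <- grep("^member[0-9]+$", names(df), value = TRUE)
  override_cols <- intersect(TRAIT_ORDER, names(df))
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    members <- unlist(df[i, member_cols], use.names = FALSE)
    members <- members[!is.na(members) & nzchar(members)]
    ov <- NULL
    for (tr in override_cols) {
      cell <- trimws(df[i, tr])
      if (!nzchar(cell)) next
      ov[[tr]] <- if (toupper(cell) == "NA") NA_real_ else as.numeric(cell)
    }
    out[[i]] <- average_composite(db, df$composite_code[[i]], members,
                                  overrides = ov)
  }
  do.call(rbind_fill, out)
}

# rbind data frames with possibly different columns (base-only fill with NA)
rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (nm in setdiff(cols, names(d))) d[[nm]] <- NA
    d[, cols, drop = FALSE]
  })
  do.call(rbind, dfs)
}

#' Organise raw counts into per-sample averaged trait profiles
#'
#' The core data-organisation step: converts the count matrix to
#' presence/absence, merges composite-taxon trait records and any VEGPROP
#' overrides into a working copy of the database, attaches flowering periods
#' (models 1 and 3 only), and averages each model-relevant trait over the taxa
#' present in each sample. The per-trait denominator is the number of
#' contributing taxa with a NON-missing value for that trait, so species whose
#' VEGPROP was blanked are excluded from the VEGPROP mean but still count for
#' every other trait.
#'
#' Taxa whose codes are absent from the working database are excluded with a
#' warning listing them (an error is raised only if nothing remains). Output
#' predictor columns follow the fixed order `SLA, ARNODE, LOGCANH, LOGCAND,
#' VEGPROP, FLOWPER`, restricted to the chosen model's predictor set.
#'
#' @param counts Raw taxa-by-samples count matrix (see [read_counts_csv()]);
#'   run [clean_samples()] first if the minimum seed filter is wanted.
#' @param db A [trait_db].
#' @param model Reference model id: 1 (input level, 5 traits), 2 (input level,
#'   4 traits) or 3 (disturbance, VEGPROP + FLOWPER).
#' @param flowper Named numeric vector of flowering periods (months) keyed by
#'   species code; required for models 1 and 3.
#' @param composites Optional data frame of composite trait records (from
#'   [average_composite()] / [read_composites_csv()], possibly with manually
#'   added rows for species missing from the database).
#' @param vegprop_overrides Optional named vector/list mapping species codes to
#'   a replacement VEGPROP value (0, 1 or `NA` to exclude the species from
#'   VEGPROP averaging).
#' @return Data frame (class `sample_profiles`): `sample`, the model's
#'   predictor columns, `n_species`, `n_seeds`, `low_diversity`. Attributes:
#'   `model`, `excluded` (codes not found), `db_version`.
#' @export
organise <- function(counts, db, model, flowper = NULL, composites = NULL,
                     vegprop_overrides = NULL) {
  validate_counts(counts)
  stopifnot(inherits(db, "trait_db"))
  if (!model %in% 1:3) stop("model must be 1, 2 or 3", call. = FALSE)
  predictors <- weed_predictors(model)

  work <- db$records
  if (!is.null(composites) && nrow(composites)) {
    composites <- as.data.frame(composites, stringsAsFactors = FALSE)
    composites$code <- tolower(composites$code)
    clash <- intersect(composites$code, work$code)
    if (length(clash))
      stop("composite codes already in database: ",
           paste(clash, collapse = ", "), call. = FALSE)
    work <- rbind_fill(work, composites)
  }
  if (!is.null(vegprop_overrides)) {
    if (!"VEGPROP" %in% names(work)) work$VEGPROP <- NA_real_
    ov_codes <- tolower(names(vegprop_overrides))
    unknown <- setdiff(ov_codes, work$code)
    if (length(unknown))
      stop("VEGPROP overrides for unknown codes: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    work$VEGPROP[match(ov_codes, work$code)] <-
      as.numeric(unlist(vegprop_overrides, use.names = FALSE))
  }

  pa <- to_presence_absence(counts)
  taxa <- rownames(pa)
  known <- taxa %in% work$code
  if (!any(known))
    stop("no taxon in the count matrix matches the trait database",
         call. = FALSE)
  excluded <- taxa[!known]
  if (length(excluded))
    warning("taxa not in trait database (excluded from profiles): ",
            paste(excluded, collapse = ", "), call. = FALSE)
  pa <- pa[known, , drop = FALSE]
  taxa <- rownames(pa)

  if ("FLOWPER" %in% predictors) {
    if (is.null(flowper))
      stop("a FLOWPER table is required for model ", model, call. = FALSE)
    names(flowper) <- tolower(names(flowper))
    no_fl <- taxa[!(taxa %in% names(flowper)) |
                    is.na(flowper[match(taxa, names(flowper))])]
    if (length(no_fl))
      stop("FLOWPER missing for taxa present in counts: ",
           paste(no_fl, collapse = ", "), call. = FALSE)
    work$FLOWPER <- flowper[match(work$code, names(flowper))]
  }
  for (tr in predictors)
    if (!tr %in% names(work)) work[[tr]] <- NA_real_

  tr_mat <- as.matrix(work[match(taxa, work$code), predictors, drop = FALSE])
  rownames(tr_mat) <- taxa

  n_species <- colSums(pa)
  n_seeds <- colSums(counts)[colnames(pa)]
  prof <- matrix(NA_real_, nrow = ncol(pa), ncol = length(predictors),
                 dimnames = list(colnames(pa), predictors))
  for (tr in predictors) {
    v <- tr_mat[, tr]
    ok <- !is.na(v)
    num <- colSums(pa[ok, , drop = FALSE] * v[ok])   # sum over present taxa
    den <- colSums(pa[ok, , drop = FALSE])           # non-missing contributors
    prof[, tr] <- ifelse(den > 0, num / den, NA_real_)
  }
  out <- data.frame(sample = colnames(pa), prof,
                    n_species = unname(n_species),
                    n_seeds = unname(n_seeds),
                    low_diversity = unname(n_species) < 3L,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, model = model, excluded = excluded,
            db_version = db$version,
            class = c("sample_profiles", "data.frame"))
}

#' Round a flowering period for display
#'
#' Composite flowering periods are kept at full precision internally and only
#' rounded to the nearest half month when shown.
#'
#' @param x Numeric months.
#' @return `x` rounded to the nearest 0.5.
#' @export
display_flowper <- function(x) round(x * 2) / 2
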