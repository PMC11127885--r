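# Species-level functional trait database: four-three species codes,
# lookup/extraction, CSV round-trip.

#' Canonical trait column order
#'
#' Predictor columns are always emitted in this order: `SLA`, `ARNODE`,
#' `LOGCANH`, `LOGCAND`, `VEGPROP`, `FLOWPER`. Downstream discriminant models
#' expect exactly this ordering.
#'
#' @format A character vector of length 6.
#' @export
TRAIT_ORDER <- c("SLA", "ARNODE", "LOGCANH", "LOGCAND", "VEGPROP", "FLOWPER")

# traits that every database record must carry non-missing
MANDATORY_TRAITS <- c("SLA", "ARNODE", "LOGCANH", "LOGCAND")

#' Build a four-three species code
#'
#' Constructs the compact species identifier used throughout the trait
#' database: the first four letters of the genus concatenated with the first
#' three letters of the specific epithet (e.g. `agrogit` for *Agrostemma
#' githago*). Genera shorter than four letters keep the full genus joined with
#' an underscore (`poa_ann` for *Poa annua*). When the candidate collides with
#' a code already in `existing`, the code is extended deterministically one
#' letter at a time: first through the remaining letters of the epithet, then
#' through the remaining letters of the genus.
#'
#' @param genus Genus name (alphabetic, non-empty).
#' @param epithet Specific epithet (alphabetic, non-empty).
#' @param existing Character vector of codes already in use; comparison is
#'   case-insensitive.
#' @return A lowercase species code not present in `existing`.
#' @examples
#' make_species_code("Agrostemma", "githago")      # "agrogit"
#' make_species_code("Poa", "annua")               # "poa_ann"
#' make_species_code("Galium", "parisiense", "galipar")
#' @export
make_species_code <- function(genus, epithet, existing = character()) {
  stopifnot(is.character(genus), length(genus) == 1L,
            is.character(epithet), length(epithet) == 1L)
  if (!nzchar(genus) || !nzchar(epithet))
    stop("genus and epithet must be non-empty", call. = FALSE)
  if (grepl("[^A-Za-z]", genus) || grepl("[^A-Za-z]", epithet))
    stop("genus and epithet must be purely alphabetic, got '",
         genus, "' / '", epithet, "'", call. = FALSE)
  g <- tolower(genus)
  e <- tolower(epithet)
  existing <- tolower(existing)
  sep <- if (nchar(g) >= 4L) "" else "_"
  gpart <- substr(g, 1L, 4L)

  # base candidate, then epithet extensions one letter at a time
  eklens <- if (nchar(e) <= 3L) nchar(e) else 3L:nchar(e)
  candidates <- paste0(gpart, sep,
                       vapply(eklens, function(k) substr(e, 1L, k), ""))
  # then extend the genus part, keeping the three-letter epithet
  if (nchar(g) > 4L) {
    gl <- vapply(5L:nchar(g), function(k) substr(g, 1L, k), "")
    candidates <- c(candidates, paste0(gl, sep, substr(e, 1L, 3L)))
  }
  candidates <- unique(candidates)
  free <- candidates[!(candidates %in% existing)]
  if (!length(free))
    stop("cannot derive a unique species code for '", genus, " ", epithet,
         "': all candidate extensions collide", call. = FALSE)
  free[[1L]]
}

#' Construct a trait database
#'
#' Wraps a data frame of per-species functional trait records. Each record is
#' keyed by a four-three species code and must carry the four mandatory
#' numeric traits (`SLA`, `ARNODE`, `LOGCANH`, `LOGCAND`). `VEGPROP` may be
#' missing (`NA`) — an explicit "no data" marker distinct from 0 — and, for
#' composite pseudo-species, may be fractional in `[0, 1]`. `FLOWPER`
#' (flowering period in months) normally travels in its own per-region table
#' but is accepted here too.
#'
#' @param records Data frame with a `code` column plus trait columns.
#' @param version Database version string (mandatory; cite it in methods
#'   sections for reproducibility).
#' @return An object of class `trait_db`.
#' @export
trait_db <- function(records, version) {
  if (missing(version) || !is.character(version) || length(version) != 1L ||
      !nzchar(version))
    stop("a non-empty database `version` string is mandatory", call. = FALSE)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"code" %in% names(records))
    stop("records must have a `code` column", call. = FALSE)
  records$code <- tolower(as.character(records$code))
  bad <- records$code[!grepl("^[a-z_]+$", records$code)]
  if (length(bad))
    stop("invalid species codes (letters and underscore only): ",
         paste(bad, collapse = ", "), call. = FALSE)
  dup <- unique(records$code[duplicated(records$code)])
  if (length(dup))
    stop("duplicate species codes: ", paste(dup, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(MANDATORY_TRAITS, names(records))
  if (length(miss))
    stop("missing mandatory trait columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (tr in MANDATORY_TRAITS) {
    records[[tr]] <- as.numeric(records[[tr]])
    if (anyNA(records[[tr]]))
      stop("trait ", tr, " has missing values for: ",
           paste(records$code[is.na(records[[tr]])], collapse = ", "),
           call. = FALSE)
  }
  if (any(records$SLA <= 0) || any(records$ARNODE <= 0))
    stop("SLA and ARNODE must be strictly positive", call. = FALSE)
  if ("VEGPROP" %in% names(records)) {
    records$VEGPROP <- as.numeric(records$VEGPROP)
    v <- records$VEGPROP[!is.na(records$VEGPROP)]
    if (any(v < 0 | v > 1))
      stop("VEGPROP values must lie in [0, 1] (0/1 for species, fractional ",
           "only for composite taxa)", call. = FALSE)
  }
  if ("FLOWPER" %in% names(records)) {
    records$FLOWPER <- as.numeric(records$FLOWPER)
    f <- records$FLOWPER[!is.na(records$FLOWPER)]
    if (any(f < 1 | f > 12))
      stop("FLOWPER must lie in [1, 12] months", call. = FALSE)
  }
  rownames(records) <- NULL
  structure(list(records = records, version = version), class = "trait_db")
}

#' @export
print.trait_db <- function(x, ...) {
  cat("<trait_db> version", x$version, "-", nrow(x$records), "species\n")
  cat("traits:", paste(intersect(c(TRAIT_ORDER, "LIFEHIST"),
                                 names(x$records)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.trait_db <- function(x) nrow(x$records)

#' Extract trait values for a set of species codes
#'
#' Returns one row per requested code found in the database, in the order the
#' codes were given, restricted to the requested traits. Codes absent from the
#' database are reported via a warning and attached to the result as the
#' `"missing"` attribute — they are never silently dropped.
#'
#' @param db A [trait_db] object.
#' @param codes Character vector of species codes (case-insensitive).
#' @param traits Optional character vector of trait/column names to return
#'   (default: all columns, including `LIFEHIST`).
#' @return Data frame of trait values with attribute `"missing"` listing
#'   unknown codes.
#' @export
weed_lookup <- function(db, codes, traits = NULL) {
  stopifnot(inherits(db, "trait_db"))
  if (!length(codes)) stop("`codes` must be non-empty", call. = FALSE)
  codes <- tolower(as.character(codes))
  known <- codes %in% db$records$code
  if (!any(known))
    stop("none of the requested codes are in the database: ",
         paste(codes, collapse = ", "), call. = FALSE)
  missing_codes <- unique(codes[!known])
  if (length(missing_codes))
    warning("codes not in trait database (excluded): ",
            paste(missing_codes, collapse = ", "), call. = FALSE)
  out <- db$records[match(codes[known], db$records$code), , drop = FALSE]
  if (!is.null(traits)) {
    unknown_tr <- setdiff(traits, names(out))
    if (length(unknown_tr))
      stop("unknown trait columns: ", paste(unknown_tr, collapse = ", "),
           call. = FALSE)
    out <- out[, c("code", setdiff(traits, "code")), drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "missing") <- missing_codes
  out
}

# metadata line written as the first line of every trait CSV
.version_line <- function(version) paste0("# trait_db_version: ", version)

#' Read / write a trait database CSV
#'
#' The file format is a plain CSV with columns
#' `code,genus,epithet,SLA,ARNODE,LOGCANH,LOGCAND,VEGPROP,LIFEHIST`
#' (flowering period travels in its own two-column file, see
#' [read_flowper_csv()]), preceded by one comment line carrying the database
#' version, e.g. `# trait_db_version: 1`. Published trait datasets without the
#' comment line can be imported by passing `version` explicitly. Writing then
#' reading reproduces every numeric value bit-exactly.
#'
#' @param path File path.
#' @param version Version string override; required when the file has no
#'   version metadata line.
#' @return [read_trait_csv()] returns a [trait_db]; [write_trait_csv()]
#'   returns `path` invisibly.
#' @export
read_trait_csv <- function(path, version = NULL) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*trait_db_version:\\s*(.+)$", first))[[1L]]
  if (length(m) == 2L) {
    version <- trimws(m[[2L]])
  } else if (is.null(version)) {
    stop("no `# trait_db_version:` metadata line in ", path,
         "; pass `version` explicitly to import an unversioned file",
         call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        check.names = FALSE)
  trait_db(df, version = version)
}

#' @rdname read_trait_csv
#' @param db A [trait_db] object.
#' @export
write_trait_csv <- function(db, path) {
  stopifnot(inherits(db, "trait_db"))
  out <- db$records
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      # 17 significant digits guarantee a bit-exact double round trip
      s <- vapply(out[[nm]], function(v)
        if (is.na(v)) "" else formatC(v, digits = 17, format = "g"), "")
      out[[nm]] <- s
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.version_line(db$version), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a flowering-period table
#'
#' Two-column CSV `species.codes,FLOWPER` (months, 1–12). Flowering period is
#' region-specific and therefore compiled per study from local Floras rather
#' than shipped with the trait database.
#'
#' @param path File path.
#' @return Named numeric vector of months keyed by species code.
#' @export
read_flowper_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L)
    stop("flowering-period CSV needs columns `species.codes,FLOWPER`",
         call. = FALSE)
  names(df)[1:2] <- c("species.codes", "FLOWPER")
  fl <- as.numeric(df$FLOWPER)
  codes <- tolower(as.character(df$species.codes))
  if (anyDuplicated(codes))
    stop("duplicate species codes in flowering-period table: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.na(fl) & (fl < 1 | fl > 12)))
    stop("FLOWPER must lie in [1, 12] months", call. = FALSE)
  stats::setNames(fl, codes)
}

#' @rdname read_flowper_csv
#' @param flowper Named numeric vector as returned by [read_flowper_csv()].
#' @export
write_flowper_csv <- function(flowper, path) {
  utils::write.csv(
    data.frame(species.codes = names(flowper), FLOWPER = unname(flowper)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
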