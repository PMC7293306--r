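#' Canonicalize drug names
#'
#' Drugs are matched case-insensitively after whitespace trimming and stored
#' lower-cased; product-label and spontaneous-report sources capitalize
#' inconsistently.
#'
#' @param x character vector of drug names.
#' @return character vector of canonical (trimmed, lower-case) names.
#' @keywords internal
canonical_drug <- function(x) {
  tolower(trimws(x))
}

#' Canonicalize MedDRA-style Preferred Term names
#'
#' Terms are trimmed and stored sentence-cased (first letter upper, rest
#' lower), so "HYPOKALAEMIA" and "hypokalaemia" collapse to one PT.
#'
#' @param x character vector of PT (or SOC) names.
#' @return character vector of canonical names.
#' @keywords internal
canonical_pt <- function(x) {
  x <- trimws(x)
  out <- paste0(toupper(substr(x, 1, 1)), tolower(substring(x, 2)))
  out[is.na(x)] <- NA_character_
  out
}

parse_frequency <- function(x) {
  x <- trimws(as.character(x))
  pct <- grepl("%$", x)
  num <- suppressWarnings(as.numeric(sub("%$", "", x)))
  num[pct] <- num[pct] / 100
  num
}

#' Read a drug-to-ADR frequency table
#'
#' Reads the knowledge-base table of per-drug ADR average frequencies: a
#' UTF-8 tab-separated file with header `drug  pt  frequency`, one row per
#' (drug, Preferred Term) pair. Frequencies are proportions in \[0, 1\]; a
#' trailing `%` is accepted and divided by 100. Names are canonicalized
#' (drugs lower-case, PTs sentence-case). Duplicate (drug, PT) rows after
#' canonicalization are merged under `merge_policy`.
#'
#' @param path path to the tab-separated table.
#' @param merge_policy how to merge duplicate (drug, PT) rows: `"max"`
#'   (default, conservative worst-case frequency) or `"mean"`.
#' @return a data.frame with columns `drug`, `pt`, `frequency`.
#' @seealso [read_soc_map()], [knowledge_base()], [apply_harmonization()]
#' @export
read_drug_adr_table <- function(path, merge_policy = c("max", "mean")) {
  merge_policy <- match.arg(merge_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (col in c("drug", "pt", "frequency")) {
    if (!col %in% names(df)) {
      stop("drug-ADR table is missing required column '", col, "'")
    }
  }
  freq <- parse_frequency(df$frequency)
  bad <- which(is.na(freq) | freq < 0 | freq > 1)
  if (length(bad)) {
    stop("invalid frequency (must be in [0,1]) at row ", bad[1L],
         ": '", df$frequency[bad[1L]], "'")
  }
  records <- data.frame(drug = canonical_drug(df$drug),
                        pt = canonical_pt(df$pt),
                        frequency = freq,
                        stringsAsFactors = FALSE)
  if (any(!nzchar(records$drug)) || any(!nzchar(records$pt))) {
    stop("empty drug or PT name in drug-ADR table")
  }
  merge_duplicate_records(records, merge_policy)
}

merge_duplicate_records <- function(records, merge_policy) {
  key <- paste(records$drug, records$pt, sep = "\r")
  if (!anyDuplicated(key)) {
    rownames(records) <- NULL
    return(records)
  }
  fun <- if (merge_policy == "max") max else mean
  agg <- tapply(records$frequency, key, fun)
  first <- !duplicated(key)
  out <- records[first, , drop = FALSE]
  out$frequency <- as.numeric(agg[key[first]])
  rownames(out) <- NULL
  out
}

#' Write a drug-to-ADR frequency table
#'
#' Inverse of [read_drug_adr_table()]: round-trips records exactly (names
#' bit-exact, frequencies to full double precision).
#'
#' @param records data.frame with columns `drug`, `pt`, `frequency`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_drug_adr_table <- function(records, path) {
  df <- data.frame(drug = records$drug, pt = records$pt,
                   frequency = format(records$frequency, digits = 17,
                                      scientific = FALSE, trim = TRUE),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Preferred Term to System Organ Class map
#'
#' Two-column UTF-8 tab-separated file with header `pt  soc`. Every PT must
#' map to exactly one SOC; repeated identical rows are deduplicated, and a
#' PT mapped to two different SOCs is an error.
#'
#' @param path path to the tab-separated map.
#' @return named character vector: `soc_map[pt] == soc`.
#' @export
read_soc_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (col in c("pt", "soc")) {
    if (!col %in% names(df)) {
      stop("SOC map is missing required column '", col, "'")
    }
  }
  pt <- canonical_pt(df$pt)
  soc <- canonical_pt(df$soc)
  dup <- !duplicated(paste(pt, soc, sep = "\r"))
  pt <- pt[dup]; soc <- soc[dup]
  conflict <- pt[duplicated(pt)]
  if (length(conflict)) {
    stop("PT mapped to multiple SOCs: ", paste(unique(conflict), collapse = ", "))
  }
  stats::setNames(soc, pt)
}

#' Read a PT harmonization map
#'
#' UTF-8 tab-separated file with header `synonym  canonical`, mapping
#' synonym Preferred Terms onto the canonical term used in the knowledge
#' base. The map must be idempotent: no canonical term may itself appear as
#' a synonym.
#'
#' @param path path to the tab-separated map.
#' @return named character vector: `map[synonym] == canonical`.
#' @export
read_harmonization_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (col in c("synonym", "canonical")) {
    if (!col %in% names(df)) {
      stop("harmonization map is missing required column '", col, "'")
    }
  }
  map <- stats::setNames(canonical_pt(df$canonical), canonical_pt(df$synonym))
  validate_harmonization_map(map)
  map
}

validate_harmonization_map <- function(map) {
  if (anyDuplicated(names(map))) {
    stop("harmonization map has duplicated synonym entries")
  }
  bad <- intersect(unname(map), names(map))
  if (length(bad)) {
    stop("harmonization map is not idempotent; canonical term(s) also ",
         "listed as synonyms: ", paste(bad, collapse = ", "))
  }
  invisible(map)
}

#' Harmonize ADR term synonyms in a frequency table
#'
#' Renames every record whose PT is a synonym in `map` to its canonical
#' term, then merges any (drug, PT) collisions created by the renaming.
#' Applying the same map twice is a no-op (the map is required to be
#' idempotent).
#'
#' @param records data.frame with columns `drug`, `pt`, `frequency`.
#' @param map named character vector, `synonym -> canonical`. An empty map
#'   is a no-op.
#' @param merge_policy `"max"` (default) or `"mean"` for merged collisions.
#' @return records with unique (drug, PT) pairs and no synonym PTs.
#' @export
apply_harmonization <- function(records, map,
                                merge_policy = c("max", "mean")) {
  merge_policy <- match.arg(merge_policy)
  if (length(map) == 0L) {
    rownames(records) <- NULL
    return(records)
  }
  validate_harmonization_map(map)
  hit <- records$pt %in% names(map)
  records$pt[hit] <- unname(map[records$pt[hit]])
  merge_duplicate_records(records, merge_policy)
}

#' Assemble a knowledge base
#'
#' Bundles the harmonized drug-to-ADR frequency records and the PT-to-SOC
#' map into the `adr_kb` object the scoring pipeline queries. Every PT in
#' the records must be covered by the SOC map.
#'
#' @param records data.frame with columns `drug`, `pt`, `frequency`
#'   (typically from [read_drug_adr_table()] after
#'   [apply_harmonization()]).
#' @param soc_map named character vector from [read_soc_map()].
#' @return an object of class `adr_kb` with elements `records` and
#'   `soc_map`.
#' @examples
#' recs <- data.frame(drug = c("druga", "druga", "drugb"),
#'                    pt = c("Nausea", "Rash", "Nausea"),
#'                    frequency = c(0.10, 0.02, 0.25))
#' socs <- c(Nausea = "Gastrointestinal disorders", Rash = "Skin disorders")
#' kb <- knowledge_base(recs, socs)
#' candidate_adr_profile(c("drugA", "drugB"), kb)
#' @export
knowledge_base <- function(records, soc_map) {
  stopifnot(is.data.frame(records),
            all(c("drug", "pt", "frequency") %in% names(records)))
  if (any(records$frequency < 0 | records$frequency > 1)) {
    stop("knowledge-base frequencies must lie in [0,1]")
  }
  names(soc_map) <- canonical_pt(names(soc_map))
  soc_map[] <- canonical_pt(soc_map)
  records$drug <- canonical_drug(records$drug)
  records$pt <- canonical_pt(records$pt)
  missing_soc <- setdiff(unique(records$pt), names(soc_map))
  if (length(missing_soc)) {
    stop("PT(s) missing from the SOC map: ",
         paste(missing_soc, collapse = ", "))
  }
  if (anyDuplicated(paste(records$drug, records$pt, sep = "\r"))) {
    stop("duplicate (drug, PT) pairs; harmonize/merge before assembling")
  }
  rownames(records) <- NULL
  structure(list(records = records, soc_map = soc_map), class = "adr_kb")
}

#' @export
print.adr_kb <- function(x, ...) {
  cat("ADR knowledge base\n")
  cat("  drugs:", length(unique(x$records$drug)),
      " PTs:", length(unique(x$records$pt)),
      " SOCs:", length(unique(x$soc_map)),
      " (drug, PT) pairs:", nrow(x$records), "\n")
  invisible(x)
}

#' Candidate ADR profile for a drug combination
#'
#' Collects, for a queried set of drugs, every Preferred Term listed for at
#' least one of them, together with the per-drug frequencies contributing
#' to that PT's frequency score. Drugs absent from the knowledge base
#' contribute nothing and are reported via a warning, so partial knowledge
#' bases remain usable.
#'
#' @param drugs character vector of drug names (matched case-insensitively).
#' @param kb an `adr_kb` object.
#' @return a list of per-PT entries, each a list with `pt`, `soc`, and
#'   `contributions` (data.frame of `drug`, `frequency`), ordered by PT.
#' @export
candidate_adr_profile <- function(drugs, kb) {
  stopifnot(inherits(kb, "adr_kb"))
  drugs <- unique(canonical_drug(drugs))
  drugs <- drugs[nzchar(drugs)]
  if (length(drugs) == 0L) return(list())
  unknown <- setdiff(drugs, unique(kb$records$drug))
  if (length(unknown)) {
    warning("drug(s) not in the knowledge base: ",
            paste(unknown, collapse = ", "))
  }
  sub <- kb$records[kb$records$drug %in% drugs, , drop = FALSE]
  if (nrow(sub) == 0L) return(list())
  pts <- sort(unique(sub$pt))
  out <- lapply(pts, function(p) {
    rows <- sub[sub$pt == p, , drop = FALSE]
    list(pt = p,
         soc = unname(kb$soc_map[p]),
         contributions = data.frame(drug = rows$drug,
                                    frequency = rows$frequency,
                                    stringsAsFactors = FALSE))
  })
  names(out) <- pts
  out
}
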