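#' Construct a fingerprint panel
#'
#' A fingerprint panel is the ordered set of tumor-specific SNV sites tracked
#' by a tumor-informed ctDNA assay (e.g. a bespoke 98- or 1822-site panel
#' designed from tumor/normal sequencing). Site identifiers are authoritative
#' for all joins; genomic coordinates are carried as annotation only and use
#' the 0-based half-open BED convention.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 0-based start coordinates (end = pos + 1).
#' @param ref_allele,alt_allele single-base reference and alternate alleles.
#' @param site_id unique site identifiers; defaults to `chrom:pos:ref>alt`.
#' @param name identifier string for the panel.
#'
#' @return An object of class `panel_fingerprint`: a data.frame with columns
#'   `chrom`, `pos`, `ref_allele`, `alt_allele`, `site_id` and attribute
#'   `panel_name`. Row order is the panel order and is stable across
#'   read/write round trips.
#' @export
#' @examples
#' panel_fingerprint(c("chr1", "chr2"), c(100L, 200L), c("A", "C"), c("T", "G"))
panel_fingerprint <- function(chrom, pos, ref_allele, alt_allele,
                              site_id = NULL, name = "panel") {
  if (is.null(site_id)) {
    site_id <- sprintf("%s:%d:%s>%s", chrom, as.integer(pos),
                       ref_allele, alt_allele)
  }
  panel <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref_allele = as.character(ref_allele),
    alt_allele = as.character(alt_allele),
    site_id = as.character(site_id),
    stringsAsFactors = FALSE
  )
  attr(panel, "panel_name") <- name
  class(panel) <- c("panel_fingerprint", "data.frame")
  validate_panel(panel)
}

#' Validate a fingerprint panel
#'
#' Checks the panel invariants: at least one site, unique site identifiers,
#' non-negative coordinates, and ref != alt at every site.
#'
#' @param panel a `panel_fingerprint`.
#' @return The panel, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_panel <- function(panel) {
  if (nrow(panel) < 1L) {
    stop("panel must contain at least one site", call. = FALSE)
  }
  dup <- duplicated(panel$site_id)
  if (any(dup)) {
    stop("duplicate site_id in panel: ",
         paste(unique(panel$site_id[dup]), collapse = ", "), call. = FALSE)
  }
  if (any(panel$pos < 0L, na.rm = TRUE)) {
    stop("panel positions must be >= 0 (0-based BED convention)",
         call. = FALSE)
  }
  bad <- panel$ref_allele == panel$alt_allele
  if (any(bad)) {
    stop("ref_allele equals alt_allele at site(s): ",
         paste(panel$site_id[bad], collapse = ", "), call. = FALSE)
  }
  panel
}

#' @export
print.panel_fingerprint <- function(x, ...) {
  cat(sprintf("panel_fingerprint '%s': %d SNV sites\n",
              attr(x, "panel_name") %||% "panel", nrow(x)))
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("... and %d more sites\n", nrow(x) - 5L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a fingerprint panel from a BED-like TSV
#'
#' Expected format: tab-separated columns `chrom, start, end, ref, alt,
#' site_id` (6 columns) or `chrom, start, ref, alt` (4-column variant list,
#' site ids auto-generated). Lines starting with `#` are comments. Coordinates
#' are 0-based half-open; for SNVs `end == start + 1`.
#'
#' @param path path to the panel file.
#' @param name panel identifier; defaults to the file name.
#' @return A [panel_fingerprint()] with sites in file order.
#' @export
read_panel <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("panel file has no data lines: ", path,
                                call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (!all(nf %in% c(4L, 6L)) || length(unique(nf)) != 1L) {
    bad <- lineno[which(nf != nf[1L] | !(nf %in% c(4L, 6L)))][1L]
    stop(sprintf("malformed panel line %d in %s: expected 4 or 6 tab-separated fields",
                 bad, path), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  if (nf[1L] == 6L) {
    start <- suppressWarnings(as.integer(m[, 2L]))
    end <- suppressWarnings(as.integer(m[, 3L]))
    if (anyNA(start) || anyNA(end)) {
      bad <- lineno[which(is.na(start) | is.na(end))][1L]
      stop(sprintf("malformed panel line %d in %s: non-integer coordinate",
                   bad, path), call. = FALSE)
    }
    if (any(end != start + 1L)) {
      bad <- lineno[which(end != start + 1L)][1L]
      stop(sprintf("malformed panel line %d in %s: SNV interval must have end == start + 1",
                   bad, path), call. = FALSE)
    }
    panel_fingerprint(m[, 1L], start, m[, 4L], m[, 5L], m[, 6L], name = name)
  } else {
    start <- suppressWarnings(as.integer(m[, 2L]))
    if (anyNA(start)) {
      bad <- lineno[which(is.na(start))][1L]
      stop(sprintf("malformed panel line %d in %s: non-integer coordinate",
                   bad, path), call. = FALSE)
    }
    panel_fingerprint(m[, 1L], start, m[, 3L], m[, 4L], name = name)
  }
}

#' Write a fingerprint panel to a BED-like TSV
#'
#' Emits the 6-column format read by [read_panel()]: `chrom, start, end, ref,
#' alt, site_id`, UTF-8, tab-delimited, newline-terminated, no header.
#'
#' @param panel a `panel_fingerprint`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  out <- data.frame(panel$chrom, panel$pos, panel$pos + 1L,
                    panel$ref_allele, panel$alt_allele, panel$site_id)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
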