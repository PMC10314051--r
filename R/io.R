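#' @keywords internal
"_PACKAGE"

# Fixed ordinal coding of the histological progression axis. The coding is
# total: every recognised label has exactly one rank.
HISTOLOGY_RANKS <- c(
  normal               = 1L,
  transition           = 2L,
  low_grade_dysplasia  = 3L,
  high_grade_dysplasia = 4L,
  carcinoma            = 5L
)

SEGMENT_LEVELS <- c("PanCK", "Vimentin")
PROBE_CLASSES <- c("target", "negative", "ntc")

#' Ordinal rank of a histology label
#'
#' Maps histology labels onto the ordered progression axis
#' normal (1) -> transition (2) -> low-grade dysplasia (3) ->
#' high-grade dysplasia (4) -> carcinoma (5).
#'
#' @param histology Character vector of histology labels.
#' @return Integer vector of ranks in 1..5.
#' @examples
#' histology_rank(c("normal", "carcinoma"))
#' @export
histology_rank <- function(histology) {
  bad <- setdiff(unique(histology), names(HISTOLOGY_RANKS))
  if (length(bad)) {
    stop("unknown histology label(s): ", paste(bad, collapse = ", "),
         "; expected one of: ", paste(names(HISTOLOGY_RANKS), collapse = ", "))
  }
  unname(HISTOLOGY_RANKS[histology])
}

#' Construct a probe-level count matrix
#'
#' The probe count matrix is the raw unit of a DSP run: one row per panel
#' probe (target probes, negative probes measuring nonspecific binding, and
#' no-template PCR controls), one column per area of illumination (AOI).
#'
#' @param counts Numeric matrix of non-negative integer counts,
#'   probes x AOIs. Row names are probe ids, column names AOI ids.
#' @param probe_meta Data frame with columns `probe_id`, `target`
#'   (gene symbol, or control name for non-target probes) and `probe_class`
#'   (one of `"target"`, `"negative"`, `"ntc"`), one row per row of `counts`.
#' @return An object of class `probe_counts`.
#' @export
probe_counts <- function(counts, probe_meta) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (!all(c("probe_id", "target", "probe_class") %in% names(probe_meta)))
    stop("probe_meta must have columns probe_id, target, probe_class")
  probe_meta <- as.data.frame(probe_meta, stringsAsFactors = FALSE)
  if (nrow(probe_meta) != nrow(counts))
    stop("probe_meta rows (", nrow(probe_meta), ") != count rows (", nrow(counts), ")")
  if (anyDuplicated(probe_meta$probe_id))
    stop("duplicate probe_id: ",
         paste(unique(probe_meta$probe_id[duplicated(probe_meta$probe_id)]), collapse = ", "))
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("counts must have unique AOI column names")
  bad_class <- setdiff(unique(probe_meta$probe_class), PROBE_CLASSES)
  if (length(bad_class))
    stop("unknown probe_class: ", paste(bad_class, collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and >= 0")
  if (any(counts != floor(counts)))
    stop("counts must be integers; first offending row index: ",
         which(rowSums(counts != floor(counts)) > 0)[1])
  if (!any(probe_meta$probe_class == "negative"))
    stop("at least one negative-class probe is required (LOQ and background QC)")
  rownames(counts) <- probe_meta$probe_id
  structure(list(counts = counts, probes = probe_meta),
            class = "probe_counts")
}

#' @export
print.probe_counts <- function(x, ...) {
  tab <- table(x$probes$probe_class)
  cat("probe_counts: ", nrow(x$counts), " probes x ", ncol(x$counts), " AOIs (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.probe_counts <- function(x) dim(x$counts)

#' AOI ids of a probe count matrix
#' @param x A `probe_counts` object.
#' @return Character vector of AOI ids (column order preserved).
#' @export
aoi_ids <- function(x) colnames(x$counts)

.infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a probe-level count table
#'
#' Reads a delimited text file (TSV or CSV, header row required) with probe
#' metadata columns `probe_id`, `target`, `probe_class` followed by one
#' count column per AOI. Row and column order are preserved.
#'
#' @param path Path to the file.
#' @param sep Field separator; inferred from the extension by default.
#' @return A [probe_counts] object.
#' @export
read_probe_counts <- function(path, sep = .infer_sep(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  req <- c("probe_id", "target", "probe_class")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  meta <- df[req]
  count_cols <- setdiff(names(df), req)
  if (!length(count_cols)) stop("no AOI count columns found")
  counts <- as.matrix(df[count_cols])
  if (!is.numeric(counts)) {
    bad <- which(!vapply(df[count_cols], is.numeric, logical(1)))[1]
    stop("non-numeric counts in column: ", count_cols[bad])
  }
  bad_rows <- which(rowSums(!is.finite(counts) | counts < 0 | counts != floor(counts)) > 0)
  if (length(bad_rows))
    stop("negative or non-integer count at row ", bad_rows[1])
  colnames(counts) <- count_cols
  probe_counts(counts, meta)
}

#' Write a probe-level count table
#' @param x A [probe_counts] object.
#' @param path Output path (TSV or CSV by extension).
#' @return `path`, invisibly.
#' @export
write_probe_counts <- function(x, path) {
  df <- cbind(x$probes[c("probe_id", "target", "probe_class")],
              as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(df, path, sep = .infer_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an AOI annotation table
#'
#' One row per AOI with sample/ROI/segment identity, the histology label of
#' the parent ROI, and the technical metrics consumed by AOI QC.
#'
#' @param path Path to a TSV/CSV file with columns `aoi_id`, `sample_id`,
#'   `roi_id`, `segment`, `histology`, `nuclei`, `area`, `raw_reads`,
#'   `pct_aligned`, `seq_saturation`, `ntc_count`.
#' @param sep Field separator; inferred from the extension by default.
#' @return A data frame with an added integer `histology_rank` column.
#' @export
read_aoi_annotation <- function(path, sep = .infer_sep(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  ann <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  validate_aoi_annotation(ann)
}

#' Validate an AOI annotation data frame
#' @param ann Data frame of AOI annotations (see [read_aoi_annotation]).
#' @return The validated annotation with a `histology_rank` column.
#' @export
validate_aoi_annotation <- function(ann) {
  req <- c("aoi_id", "sample_id", "roi_id", "segment", "histology",
           "nuclei", "area", "raw_reads", "pct_aligned", "seq_saturation",
           "ntc_count")
  missing_cols <- setdiff(req, names(ann))
  if (length(missing_cols))
    stop("missing annotation column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(ann$aoi_id))
    stop("duplicate aoi_id in annotation")
  bad_seg <- setdiff(unique(ann$segment), SEGMENT_LEVELS)
  if (length(bad_seg))
    stop("unknown segment label(s): ", paste(bad_seg, collapse = ", "))
  ann$histology_rank <- histology_rank(ann$histology)
  if (any(ann$area <= 0)) stop("area must be > 0")
  if (any(ann$nuclei < 0)) stop("nuclei must be >= 0")
  pct <- c(ann$pct_aligned, ann$seq_saturation)
  if (any(pct < 0 | pct > 100)) stop("percentages must lie in [0, 100]")
  ann
}

#' Write an AOI annotation table
#' @param ann Annotation data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aoi_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = .infer_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: name TAB description TAB gene TAB gene ... Duplicate
#' genes within a set are removed with a warning.
#'
#' @param path Path to the GMT file.
#' @return An object of class `gene_set_collection`: a list with elements
#'   `sets` (named list of character vectors) and `source`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("GMT parse error: line ", which(nf < 3)[1], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) stop("duplicate gene-set name: ",
                              nm[duplicated(nm)][1])
  sets <- lapply(fields, function(f) {
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene(s) within set '", f[[1]], "' removed",
              call. = FALSE)
      genes <- unique(genes)
    }
    genes
  })
  names(sets) <- nm
  gene_set_collection(sets, source = path)
}

#' Construct a gene-set collection
#' @param sets Named list of character vectors of gene symbols.
#' @param source Free-text provenance.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, source = "in-memory") {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names")
  if (any(lengths(sets) == 0)) stop("empty gene set: ",
                                    names(sets)[lengths(sets) == 0][1])
  structure(list(sets = sets, source = source), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection: ", length(x$sets), " sets (",
      min(lengths(x$sets)), "-", max(lengths(x$sets)), " genes), source: ",
      x$source, "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Write a gene-set collection as GMT
#' @param x A `gene_set_collection`.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path, description = "na") {
  lines <- vapply(names(x$sets), function(nm) {
    paste(c(nm, description, x$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table
#' @param res A result data frame (see [paired_segment_de] and friends).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
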