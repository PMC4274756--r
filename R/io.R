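#' Read gene models from GFF3 or BED
#'
#' Parses gene-level records into the internal 1-based inclusive coordinate
#' convention. BED input (0-based half-open) is converted on read
#' (start + 1, end); GFF3 coordinates are taken as-is.
#'
#' @param path Path to the gene-model file.
#' @param format `"gff3"` or `"bed"`. Guessed from the file extension when
#'   omitted.
#' @return A [genome_gene_set].
#' @export
read_gene_models <- function(path, format = c("guess", "gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene-model file not found: ", path)
  if (format == "guess") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  validate_tabular_lines(path, format)
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3") {
    if ("type" %in% names(S4Vectors::mcols(gr))) {
      gr <- gr[as.character(gr$type) == "gene"]
    }
    if (length(gr) == 0) stop("no gene-level records in ", path)
    ids <- as.character(gr$ID)
    if (anyNA(ids)) {
      nm <- S4Vectors::mcols(gr)$Name
      ids[is.na(ids)] <- as.character(nm[is.na(ids)])
    }
    if (anyNA(ids)) stop("gene record without ID attribute in ", path)
  } else {
    ids <- as.character(gr$name)
    if (is.null(gr$name) || anyNA(ids)) {
      stop("BED record without a name field in ", path)
    }
  }
  genome_gene_set(data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  ))
}

# Cheap structural pre-check so malformed input fails with a line number
# rather than deep inside the importer.
validate_tabular_lines <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  min_fields <- if (format == "bed") 4L else 9L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#") || startsWith(ln, "track") ||
        startsWith(ln, "browser")) {
      next
    }
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    coord_idx <- if (format == "bed") 2:3 else 4:5
    if (length(fields) < min_fields ||
        anyNA(suppressWarnings(as.integer(fields[coord_idx])))) {
      stop(sprintf("malformed %s record at line %d of %s",
                   toupper(format), i, path))
    }
  }
  invisible(TRUE)
}

#' Read a QTL compendium from TSV
#'
#' Expects a header row with columns `trait`, `chrom`, `start`, `end` and
#' optionally `region_id`. Coordinates are 1-based inclusive.
#'
#' @param path Path to the TSV file.
#' @return A [qtl_compendium].
#' @export
read_qtl_regions <- function(path) {
  if (!file.exists(path)) stop("QTL file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("QTL file is empty: ", path)
  st <- suppressWarnings(as.integer(df$start))
  en <- suppressWarnings(as.integer(df$end))
  if (anyNA(st) || anyNA(en)) {
    stop("non-integer region coordinate at row ",
         which(is.na(st) | is.na(en))[1], " of ", path)
  }
  bad <- which(st > en)
  if (length(bad) > 0) {
    stop("region with start > end at row ", bad[1], " of ", path)
  }
  qtl_compendium(df)
}

#' Read gene-to-term annotations
#'
#' @param path Path to the annotation file.
#' @param universe A [genome_gene_set]; annotations for genes outside the
#'   universe are discarded (the discard count is kept on the result and
#'   reported via `message()`).
#' @param format `"tsv2col"` (two columns `gene_id`, `term_id`, header row)
#'   or `"gaf"` (GAF 2.x; columns 2, 5 and 9 are used and only rows with
#'   aspect `P`, the biological-process aspect, are kept).
#' @return A [function_annotation].
#' @export
read_annotations <- function(path, universe, format = c("tsv2col", "gaf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "tsv2col") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "term_id") %in% names(df))) {
      # tolerate headerless two-column files
      df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
      if (ncol(df) < 2) stop("annotation TSV needs two columns: ", path)
      names(df)[1:2] <- c("gene_id", "term_id")
    }
    pairs <- df[, c("gene_id", "term_id")]
  } else {
    raw <- utils::read.delim(path, header = FALSE, comment.char = "!",
                             stringsAsFactors = FALSE)
    if (ncol(raw) < 9) stop("GAF file has fewer than 9 columns: ", path)
    bp <- raw[raw[[9]] == "P", , drop = FALSE]
    if (nrow(bp) == 0) {
      stop("no biological-process (aspect P) rows in GAF file: ", path)
    }
    pairs <- data.frame(gene_id = bp[[2]], term_id = bp[[5]],
                        stringsAsFactors = FALSE)
  }
  ann <- function_annotation(pairs, universe)
  if (ann$n_discarded > 0) {
    message(ann$n_discarded,
            " annotation pair(s) discarded (gene not in universe)")
  }
  ann
}

#' Read a plain gene list
#'
#' One gene id per line, optional second tab-separated column (e.g. a
#' transcription-factor family label). Lines starting with `#` and a header
#' line named `gene_id` are skipped.
#'
#' @param path Path to the file.
#' @return data.frame with columns `gene_id` and, when present, `family`.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(
    gene_id = vapply(parts, `[`, character(1), 1L),
    stringsAsFactors = FALSE
  )
  if (any(lengths(parts) >= 2)) {
    df$family <- vapply(parts, function(p) {
      if (length(p) >= 2) p[2] else NA_character_
    }, character(1))
  }
  if (nrow(df) > 0 && df$gene_id[1] == "gene_id") df <- df[-1, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read GWAS SNP hits
#'
#' @param path TSV with header columns `trait`, `chrom`, `pos`.
#' @return data.frame(trait, chrom, pos); zero rows is valid.
#' @export
read_snp_hits <- function(path) {
  if (!file.exists(path)) stop("SNP file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("trait", "chrom", "pos"), names(df))
  if (length(missing_cols) > 0) {
    stop("SNP file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$trait <- as.character(df$trait)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df[, c("trait", "chrom", "pos")]
}

#' Read an identifier mapping table
#'
#' Two tab-separated columns: external id, canonical gene id (e.g. RAP ids
#' to MSU locus ids). A header row named `external_id` is skipped.
#'
#' @param path Path to the mapping TSV.
#' @return data.frame(external_id, canonical_gene_id).
#' @export
read_id_mapping <- function(path) {
  if (!file.exists(path)) stop("id-mapping file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("id-mapping file needs two columns: ", path)
  names(df)[1:2] <- c("external_id", "canonical_gene_id")
  if (nrow(df) > 0 && df$external_id[1] == "external_id") {
    df <- df[-1, , drop = FALSE]
  }
  rownames(df) <- NULL
  df[, c("external_id", "canonical_gene_id")]
}

#' Apply an identifier mapping
#'
#' Exact-string lookup; ids without a mapping are reported, never silently
#' dropped.
#'
#' @param ids Character vector of external ids.
#' @param mapping data.frame as returned by [read_id_mapping()].
#' @return list with `mapped` (canonical ids, mapping order preserved) and
#'   `unmapped` (input ids with no mapping entry).
#' @export
apply_id_mapping <- function(ids, mapping) {
  idx <- match(ids, mapping$external_id)
  list(
    mapped = unname(mapping$canonical_gene_id[idx[!is.na(idx)]]),
    unmapped = ids[is.na(idx)]
  )
}

#' Write a data.frame as TSV
#'
#' Tab-separated, header row, no quoting or row names; the format used for
#' every tabular output of the package.
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' @param genome A [genome_gene_set].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_models_gff3 <- function(genome, path) {
  stopifnot(inherits(genome, "genome_gene_set"))
  strand <- ifelse(genome$strand %in% c("+", "-"), genome$strand, ".")
  lines <- c(
    "##gff-version 3",
    sprintf("%s\tqtlprio\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            genome$chrom, genome$start, genome$end, strand, genome$gene_id)
  )
  writeLines(lines, path)
  invisible(path)
}
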