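#' Read genomic feature intervals from BED or GFF3
#'
#' Intervals are normalised to the package-wide 1-based inclusive
#' convention: BED input (0-based half-open) is shifted on read, GFF3 is
#' already 1-based inclusive. Labels come from the BED name column or the
#' GFF3 Name/ID attribute. BED3+ is parsed by a strict
#' built-in reader (so malformed lines are reported with their line
#' number); GFF3 parsing is delegated to \code{rtracklayer::import}.
#'
#' @param path file path.
#' @param dialect `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return data.frame (chrom, start, end, label); empty with a warning for
#'   an empty file.
#' @export
read_intervals <- function(path, dialect = c("auto", "bed", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, bed = "bed", gff = "gff3", gff3 = "gff3",
                      stop("cannot infer dialect from extension '", ext,
                           "'; pass dialect explicitly"))
  }
  lines <- readLines(path)
  body <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(body)) {
    warning("empty interval file: ", path)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), label = character()))
  }
  if (dialect == "bed") {
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
      stop("malformed BED line ", which(nf < 3L)[1L] +
             sum(grepl("^(#|track|browser)", lines) | !nzchar(lines)),
           ": fewer than 3 fields")
    start0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
    end0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
    bad <- which(is.na(start0) | is.na(end0))
    if (length(bad))
      stop("malformed BED line ", bad[1L], ": non-integer coordinates")
    data.frame(chrom = vapply(fields, `[`, "", 1L),
               start = start0 + 1L, end = end0,
               label = ifelse(nf >= 4L,
                              vapply(fields, function(f)
                                if (length(f) >= 4L) f[4L] else NA_character_,
                                ""), NA_character_),
               stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("GFF3 reading requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "gff3")
    md <- as.data.frame(gr)
    label <- if ("Name" %in% names(md) && any(!is.na(md$Name))) md$Name
    else if ("ID" %in% names(md)) md$ID else as.character(md$type)
    data.frame(chrom = as.character(md$seqnames), start = md$start,
               end = md$end, label = as.character(label),
               stringsAsFactors = FALSE)
  }
}

#' Read and write per-position depth tables (samtools-depth dialect)
#'
#' Three tab-separated columns: chromosome, 1-based position, depth.
#'
#' @param path file path.
#' @return data.frame (chrom, pos, depth).
#' @export
read_depth_table <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) != 3L) stop("depth table must have exactly 3 columns")
  data.table::setnames(dt, c("chrom", "pos", "depth"))
  if (!is.numeric(dt$depth) || any(dt$depth != floor(dt$depth)))
    stop("non-integer depth values")
  if (any(dt$depth < 0)) stop("negative depth values")
  if (anyDuplicated(dt, by = c("chrom", "pos")))
    stop("duplicate (chrom, pos) rows")
  as.data.frame(dt)
}

#' @rdname read_depth_table
#' @param depth depth table to write.
#' @export
write_depth_table <- function(depth, path) {
  data.table::fwrite(depth[, c("chrom", "pos", "depth")], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read and write pileup base-count tables
#'
#' Tab-separated with header: chrom, pos, ref, A, C, G, T.
#' @param path file path.
#' @export
read_pileup_table <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t"))
  req <- c("chrom", "pos", "ref", "A", "C", "G", "T")
  if (!all(req %in% names(dt))) stop("pileup table lacks required columns")
  if (!all(dt$ref %in% c("A", "C", "G", "T"))) stop("invalid reference bases")
  if (any(as.matrix(dt[, c("A", "C", "G", "T")]) < 0)) stop("negative counts")
  dt
}

#' @rdname read_pileup_table
#' @param pileup pileup table to write.
#' @export
write_pileup_table <- function(pileup, path) {
  data.table::fwrite(pileup[, c("chrom", "pos", "ref", "A", "C", "G", "T")],
                     path, sep = "\t")
  invisible(path)
}

#' Generic TSV/CSV helpers for the package's tabular outputs
#' @param path file path.
#' @param table data.frame to write.
#' @export
write_tsv_table <- function(table, path) {
  data.table::fwrite(table, path, sep = "\t")
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Write SNV calls as a minimal VCF 4.2
#'
#' One record per call with INFO fields DP (depth) and AF (alternative
#' allele fraction); enough for interchange with standard VCF consumers.
#'
#' @param snvs SNV call table from [call_snvs()].
#' @param path output path.
#' @export
write_snv_vcf <- function(snvs, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alt allele fraction\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%.4f",
                  snvs$chromosome, snvs$position, snvs$ref, snvs$alt,
                  snvs$depth, snvs$alt_fraction)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' One `key: value` pair per line (a YAML-compatible flat subset); `#`
#' comments and blank lines are ignored. Values are auto-typed (logical,
#' numeric, else character); comma-separated values become vectors.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^([^:]+):\\s*(.*)$", lines[i]))[[1L]]
    if (length(m) != 3L) stop("malformed config line: ", lines[i])
    key <- trimws(m[2L]); raw <- trimws(m[3L])
    vals <- trimws(strsplit(raw, ",", fixed = TRUE)[[1L]])
    typed <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!anyNA(typed)) typed
    else if (all(tolower(vals) %in% c("true", "false")))
      as.logical(toupper(vals))
    else vals
  }
  out
}
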