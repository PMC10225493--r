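# Readers and writers for the plain-text formats the pipeline consumes and
# emits. FASTA goes through Biostrings; BED/GFF3/bedGraph through rtracklayer;
# tables through data.table. FASTQ ingest is a small validating line parser so
# malformed records can be reported by record index (the error contract), and
# the VCF emitted by the simulators is plain VCFv4.2 text.

#' Write sequences to a 60-column wrapped FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  # keep only the first whitespace-delimited token of each header
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write reads to FASTQ (optionally gzipped)
#'
#' Quality strings are constant `I` (Phred+33 Q40); the pipeline never uses
#' base qualities.
#'
#' @param reads Named character vector (names become read ids).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(!is.null(names(reads)) || length(reads) == 0)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(reads)) {
    qual <- vapply(nchar(reads), function(n) strrep("I", n), "")
    writeLines(paste0("@", names(reads), "\n", reads, "\n+\n", qual), con,
               sep = "\n")
  }
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ path (`.gz` accepted).
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) return(setNames(character(), character()))
  if (n %% 4L != 0L)
    stop("malformed FASTQ: truncated record ", n %/% 4L + 1L, " in ", path)
  hd <- lines[seq(1L, n, by = 4L)]
  sq <- lines[seq(2L, n, by = 4L)]
  pl <- lines[seq(3L, n, by = 4L)]
  bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+"))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1L], " in ", path)
  ql <- lines[seq(4L, n, by = 4L)]
  bad <- which(nchar(ql) != nchar(sq))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1L], ": quality/sequence length mismatch")
  setNames(sq, sub("^@", "", sub("\\s.*$", "", hd)))
}

# resolve a reads argument that may be an in-memory vector or FASTQ path(s)
as_reads <- function(reads) {
  if (is.character(reads) && length(reads) >= 1 &&
      all(file.exists(reads)) && any(grepl("\\.(fq|fastq)(\\.gz)?$", reads))) {
    return(do.call(c, lapply(reads, read_fastq)))
  }
  reads
}

#' Write a dosage matrix as a multi-sample VCFv4.2 file
#'
#' Sites are emitted with `GT`-only genotypes (`0/0`, `0/1`, `1/1`, `./.`),
#' contig header lines, and 1-based positions.
#'
#' @param geno Integer matrix, sites x samples; alt-allele dosage 0/1/2 or NA.
#' @param chrom Chromosome name (scalar or per-site vector).
#' @param pos 1-based positions, strictly increasing per chromosome.
#' @param ref,alt REF and ALT allele strings per site.
#' @param samples Sample names (defaults to `colnames(geno)`).
#' @param contig_lengths Named vector for `##contig` headers (optional).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, chrom, pos, ref, alt, samples = colnames(geno),
                      contig_lengths = NULL, path) {
  n <- nrow(geno)
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n,
            !is.null(samples))
  chrom <- rep_len(chrom, n)
  gt <- matrix("./.", n, ncol(geno))
  gt[!is.na(geno) & geno == 0L] <- "0/0"
  gt[!is.na(geno) & geno == 1L] <- "0/1"
  gt[!is.na(geno) & geno == 2L] <- "1/1"
  hdr <- c("##fileformat=VCFv4.2",
           "##source=dioscan",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths),
                          as.integer(contig_lengths)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(chrom, format(pos, scientific = FALSE, trim = TRUE), ".",
                ref, alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, if (n) body), path)
  invisible(path)
}

#' Read genotype dosages from a VCF file
#'
#' Parses the `GT` field of a VCFv4.2 file into an alt-allele dosage matrix.
#' Multiallelic records are retained with dosage of the first ALT allele and
#' flagged via `n_alt`.
#'
#' @param path VCF path.
#' @return A list with `geno` (sites x samples integer matrix), `chrom`,
#'   `pos` (1-based), `ref`, `alt`, `n_alt`, `samples`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("not a VCF: missing #CHROM header in ", path)
  cols <- strsplit(lines[hdr[1L]], "\t", fixed = TRUE)[[1L]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr[1L])]
  body <- body[nzchar(body)]
  if (!length(body)) {
    return(list(geno = matrix(NA_integer_, 0, length(samples)),
                chrom = character(), pos = integer(), ref = character(),
                alt = character(), n_alt = integer(), samples = samples))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  m <- t(vapply(f, function(x) x[c(1L, 2L, 4L, 5L)], character(4L)))
  fmt <- vapply(f, `[`, "", 9L)
  gt_idx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(x) match("GT", x), 1L)
  if (anyNA(gt_idx)) stop("VCF record without GT field")
  geno <- matrix(NA_integer_, length(f), length(samples))
  for (i in seq_along(f)) {
    g <- vapply(strsplit(f[[i]][-(1:9)], ":", fixed = TRUE),
                `[`, "", gt_idx[i])
    al <- strsplit(g, "[/|]")
    geno[i, ] <- vapply(al, function(a) {
      if (any(a == ".")) return(NA_integer_)
      sum(as.integer(a) > 0L)
    }, 1L)
  }
  colnames(geno) <- samples
  list(geno = geno, chrom = m[, 1L], pos = as.integer(m[, 2L]),
       ref = m[, 3L], alt = m[, 4L],
       n_alt = lengths(strsplit(m[, 4L], ",", fixed = TRUE)),
       samples = samples)
}

#' Write intervals to BED
#'
#' @param dt A data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(dt, path) {
  dt <- as.data.table(dt)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(dt))
  fwrite(dt[, cols, with = FALSE], path, sep = "\t", col.names = FALSE,
         scipen = 50)
  invisible(path)
}

#' Read a BED file
#'
#' Uses `rtracklayer`; coordinates are returned 0-based half-open.
#'
#' @param path BED path.
#' @return A `data.table` with `chrom`, `start`, `end` and any extra columns.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) dt <- cbind(dt, as.data.table(mc))
  dt
}

#' Write a sample manifest mapping samples to files and sex labels
#'
#' @param manifest A data.frame with at least `sample_id`, `sex`, and file
#'   columns.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
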