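## PLINK bed/bim/fam reader and writer.
## bed layout: magic bytes 0x6c 0x1b, mode byte 0x01 (SNP-major), then
## ceil(n/4) bytes per SNP, two bits per animal starting at the low bits:
##   00 = A1/A1 hom, 01 = missing, 10 = het, 11 = A2/A2 hom.
## Internally codes count allele A (= A1 in the bim), so 00 -> 2, 10 -> 1,
## 11 -> 0, 01 -> NA; PLINK text codes 3/4/5 used for no-calls map to NA.

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

## byte value (0..255) -> 4 genotype codes, low bit pair first
.bedLookup <- function() {
  map <- c(2L, NA_integer_, 1L, 0L)       # 2-bit value 0,1,2,3
  t(vapply(0:255, function(b) {
    map[c(bitwAnd(b, 3L), bitwAnd(bitwShiftR(b, 2L), 3L),
          bitwAnd(bitwShiftR(b, 4L), 3L), bitwAnd(bitwShiftR(b, 6L), 3L)) + 1L]
  }, integer(4)))
}

#' Read a PLINK bed/bim/fam file set
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @return A [GenotypeData-class] with codes counting the bim A1 allele
#'   (0 = BB, 1 = AB, 2 = AA); missing bed codes become `NA`.
#' @export
readPlink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  ok <- file.exists(paths)
  if (!all(ok))
    stop("missing PLINK file(s): ", paste(paths[!ok], collapse = ", "))
  fam <- read.table(paths[3], header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  bim <- read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "snp", "cm", "bp",
                                  "alleleA", "alleleB"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || !identical(raw[1:3], .bed_magic))
    stop("not a SNP-major PLINK bed file (bad magic bytes): ", paths[1])
  bpsnp <- ceiling(n / 4)
  if (length(raw) - 3L != bpsnp * m)
    stop(sprintf("bed payload has %d bytes but %d x %d genotypes need %d",
                 length(raw) - 3L, n, m, bpsnp * m))
  lut <- .bedLookup()
  bytes <- matrix(as.integer(raw[-(1:3)]), nrow = bpsnp, ncol = m)
  codes <- matrix(NA_integer_, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    g <- t(lut[bytes[, j] + 1L, , drop = FALSE])  # 4 x bpsnp, column-major
    codes[, j] <- g[seq_len(n)]
  }
  rownames(codes) <- fam[[2]]
  colnames(codes) <- bim$snp
  GenotypeData(codes, bim[, c("snp", "chrom", "bp", "alleleA", "alleleB")])
}

#' Write a PLINK bed/bim/fam file set
#'
#' @param geno a [GenotypeData-class] object.
#' @param prefix output path prefix.
#' @return invisibly, the three file paths written.
#' @export
writePlink <- function(geno, prefix) {
  stopifnot(is(geno, "GenotypeData"))
  cd <- genotypes(geno)
  mk <- markers(geno)
  if (nrow(cd) == 0L) stop("cannot write a PLINK file set with no animals")
  n <- nrow(cd); m <- ncol(cd)
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  ids <- rownames(cd)
  fam <- data.frame(fid = ids, iid = ids, pat = 0, mat = 0, sex = 0, phe = -9)
  write.table(fam, paths[3], quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = mk$chrom, snp = mk$snp, cm = 0,
                    bp = sprintf("%.0f", mk$bp),   # never scientific
                    a1 = mk$alleleA, a2 = mk$alleleB)
  write.table(bim, paths[2], quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  ## code -> 2-bit value: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  bits <- c(`0` = 3L, `1` = 2L, `2` = 0L)
  bpsnp <- ceiling(n / 4)
  pad <- bpsnp * 4L
  con <- file(paths[1], "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  for (j in seq_len(m)) {
    v <- integer(pad)                              # padding bits are 00
    cj <- cd[, j]
    v[seq_len(n)] <- ifelse(is.na(cj), 1L, bits[as.character(cj)])
    q <- matrix(v, nrow = 4)
    bytes <- q[1, ] + q[2, ] * 4L + q[3, ] * 16L + q[4, ] * 64L
    writeBin(as.raw(bytes), con)
  }
  invisible(paths)
}

#' Write a phenotype table as CSV
#'
#' @param pheno data.frame with columns `animal_id`, `value`, `hys`,
#'   `age_months` and optionally `scc`.
#' @param path output file.
#' @export
writePhenotypes <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype CSV written by [writePhenotypes()]
#'
#' @param path CSV with header.
#' @return data.frame; `hys` as character, `animal_id` as character.
#' @export
readPhenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(animal_id = "character",
                                       hys = "character"))
  ph
}
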