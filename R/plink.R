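# Minimal PLINK bed/bim/fam IO (SNP-major 2-bit codes).  Only what the
# pipeline needs: hard-call dosage matrices in and out.

# bed 2-bit codes (per SNP-major byte, low bits first):
# 00 -> 2 copies of A1, 01 -> missing, 10 -> 1 copy, 11 -> 0 copies
.BED_DECODE <- {
  dec <- matrix(NA_real_, 256, 4)
  for (b in 0:255) {
    for (s in 0:3) {
      code <- bitwAnd(bitwShiftR(b, 2L * s), 3L)
      dec[b + 1, s + 1] <- switch(as.character(code),
                                  "0" = 2, "1" = NA_real_, "2" = 1, "3" = 0)
    }
  }
  dec
}

#' Read a PLINK bed/bim/fam genotype triplet
#'
#' @param prefix Path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @return List with `genotypes` (individuals x variants dosage matrix of A1
#'   allele counts, `NA` for missing), `variants` (data frame with `chr`,
#'   `id`, `cm`, `bp`, `a1`, `a2`) and `individuals` (fam data frame).
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  variants <- read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("chr", "id", "cm", "bp", "a1", "a2"))
  individuals <- read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                            col.names = c("fid", "iid", "pat", "mat", "sex",
                                          "pheno"))
  n <- nrow(individuals)
  V <- nrow(variants)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK bed file: bad magic bytes")
  }
  if (raw[3] != as.raw(0x01)) stop("only SNP-major bed files are supported")
  bpv <- ceiling(n / 4)  # bytes per variant
  body <- as.integer(raw[-(1:3)])
  if (length(body) != bpv * V) stop("bed payload size mismatch")
  dim(body) <- c(bpv, V)
  G <- matrix(NA_real_, n, V)
  for (s in 1:4) {  # sample slot within byte
    rows <- seq(s, by = 4, length.out = bpv)
    rows <- rows[rows <= n]
    G[rows, ] <- .BED_DECODE[body[seq_along(rows), , drop = FALSE] + 1, s]
  }
  colnames(G) <- variants$id
  list(genotypes = G, variants = variants, individuals = individuals)
}

#' Write a PLINK bed/bim/fam genotype triplet
#'
#' @param genotypes Individuals x variants matrix of A1 dosages (0/1/2, `NA`
#'   for missing); fractional dosages are rounded to hard calls.
#' @param variants Data frame with columns `chr`, `id`, `bp`, `a1`, `a2`
#'   (and optionally `cm`).
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(genotypes, variants, prefix) {
  stopifnot(ncol(genotypes) == nrow(variants))
  n <- nrow(genotypes)
  V <- ncol(genotypes)
  G <- round(genotypes)
  if (any(G < 0 | G > 2, na.rm = TRUE)) stop("dosages must lie in [0, 2]")
  # dosage -> 2-bit code
  code <- matrix(1L, n, V)  # missing
  code[!is.na(G) & G == 2] <- 0L
  code[!is.na(G) & G == 1] <- 2L
  code[!is.na(G) & G == 0] <- 3L
  bpv <- ceiling(n / 4)
  pad <- bpv * 4 - n
  if (pad > 0) code <- rbind(code, matrix(3L, pad, V))  # pad slots read as 0
  dim(code) <- c(4, bpv * V)
  bytes <- code[1, ] + bitwShiftL(code[2, ], 2) + bitwShiftL(code[3, ], 4) +
    bitwShiftL(code[4, ], 6)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  cm <- if ("cm" %in% names(variants)) variants$cm else 0
  write.table(data.frame(variants$chr, variants$id, cm, variants$bp,
                         variants$a1, variants$a2),
              paste0(prefix, ".bim"), quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = "\t")
  fam <- data.frame(fid = seq_len(n), iid = seq_len(n), pat = 0, mat = 0,
                    sex = 0, pheno = -9)
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = "\t")
  invisible(prefix)
}
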