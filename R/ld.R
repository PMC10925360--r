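# LD reference panel: pairwise squared allelic correlations, heterozygosities
# and per-variant neighbor lists serving the z-score likelihood.
#
# Only r^2 (not signed r) is stored: the characteristic function of the
# z-score model depends on LD exclusively through r_jk^2, so the sign is
# mathematically redundant (asserted by a test in the likelihood module).

#' Heterozygosity under Hardy-Weinberg equilibrium
#'
#' @param p Allele frequency (or vector thereof) in `[0, 1]`.
#' @return `2 p (1 - p)`.
#' @examples
#' heterozygosity_from_freq(0.5)  # 0.5
#' @export
heterozygosity_from_freq <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("allele frequency must lie in [0, 1]")
  }
  2 * p * (1 - p)
}

#' Pairwise r2 records from a dosage matrix
#'
#' Squared Pearson correlation between dosage columns for every
#' intra-chromosomal pair within both the variant-count and the physical
#' window; pairs below `r2_min` are omitted.  Default windows mirror the
#' conventional PLINK 1.9 invocation (`--ld-window 1000000
#' --ld-window-kb 20000 --ld-window-r2 0.01`).
#'
#' @param genotypes Numeric matrix, individuals x variants, dosages in
#'   `[0, 2]`.
#' @param variants Data frame with columns `id`, `chr`, `bp`, rows aligned to
#'   the genotype columns and sorted by (chr, bp).
#' @param window_variants Maximum index distance between paired variants.
#' @param window_kb Maximum physical distance in kilobases.
#' @param r2_min Minimum r2 retained.
#' @return Data frame with columns `chr_a, bp_a, id_a, chr_b, bp_b, id_b, r2`.
#' @export
compute_ld_from_genotypes <- function(genotypes, variants,
                                      window_variants = 1e6,
                                      window_kb = 2e4, r2_min = 0.01) {
  stopifnot(is.matrix(genotypes), nrow(variants) == ncol(genotypes))
  if (any(genotypes < 0 | genotypes > 2, na.rm = TRUE)) {
    stop("dosages must lie in [0, 2]")
  }
  o <- order(variants$chr, variants$bp)
  if (!identical(o, seq_len(nrow(variants)))) {
    stop("variants must be sorted by (chr, bp)")
  }
  n <- nrow(genotypes)
  sds <- apply(genotypes, 2, sd)
  keep <- sds > 0
  if (any(!keep)) {
    warning(sum(!keep), " zero-variance variant(s) excluded from LD: ",
            paste(head(variants$id[!keep], 5), collapse = ", "))
  }
  X <- scale(genotypes[, keep, drop = FALSE])
  vk <- variants[keep, , drop = FALSE]
  V <- ncol(X)
  out <- vector("list", 0L)
  if (V >= 2L) {
    maxlag <- min(V - 1L, as.integer(window_variants))
    for (lag in seq_len(maxlag)) {
      i <- seq_len(V - lag)
      j <- i + lag
      ok <- vk$chr[i] == vk$chr[j] &
        (vk$bp[j] - vk$bp[i]) <= window_kb * 1000
      if (!any(ok)) {
        # positions are sorted: once a lag yields no admissible pair at all,
        # larger lags cannot either (within-chromosome distances only grow)
        if (all(vk$chr[i] == vk$chr[j])) break else next
      }
      i <- i[ok]; j <- j[ok]
      r <- colSums(X[, i, drop = FALSE] * X[, j, drop = FALSE]) / (n - 1)
      r2 <- r * r
      sel <- r2 >= r2_min
      if (any(sel)) {
        out[[length(out) + 1L]] <- data.frame(
          chr_a = vk$chr[i[sel]], bp_a = vk$bp[i[sel]], id_a = vk$id[i[sel]],
          chr_b = vk$chr[j[sel]], bp_b = vk$bp[j[sel]], id_b = vk$id[j[sel]],
          r2 = pmin(r2[sel], 1), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chr_a = integer(0), bp_a = numeric(0),
                      id_a = character(0), chr_b = integer(0),
                      bp_b = numeric(0), id_b = character(0),
                      r2 = numeric(0)))
  }
  do.call(rbind, out)
}

#' Parse a PLINK 1.9 `--r2` text table
#'
#' Whitespace-delimited text with header columns `CHR_A BP_A SNP_A CHR_B
#' BP_B SNP_B R2` (variable whitespace tolerated).
#'
#' @param path File path (or connection) to the table.
#' @return Data frame with columns `chr_a, bp_a, id_a, chr_b, bp_b, id_b, r2`.
#' @export
parse_plink_ld_text <- function(path) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = TRUE)
  need <- c("CHR_A", "BP_A", "SNP_A", "CHR_B", "BP_B", "SNP_B", "R2")
  miss <- setdiff(need, toupper(names(tab)))
  if (length(miss)) {
    stop("PLINK r2 table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  names(tab) <- toupper(names(tab))
  r2 <- suppressWarnings(as.numeric(tab$R2))
  if (anyNA(r2)) {
    bad <- which(is.na(r2))[1]
    stop(sprintf("unparsable R2 value '%s' on data line %d",
                 tab$R2[bad], bad))
  }
  data.frame(chr_a = as.integer(tab$CHR_A), bp_a = as.numeric(tab$BP_A),
             id_a = tab$SNP_A, chr_b = as.integer(tab$CHR_B),
             bp_b = as.numeric(tab$BP_B), id_b = tab$SNP_B, r2 = r2,
             stringsAsFactors = FALSE)
}

#' Write r2 records in the PLINK 1.9 `--r2` text dialect
#'
#' @param records Data frame as returned by [compute_ld_from_genotypes()].
#' @param path Output file path.
#' @export
write_plink_ld_text <- function(records, path) {
  out <- data.frame(CHR_A = records$chr_a, BP_A = records$bp_a,
                    SNP_A = records$id_a, CHR_B = records$chr_b,
                    BP_B = records$bp_b, SNP_B = records$id_b,
                    R2 = records$r2)
  write.table(out, path, quote = FALSE, row.names = FALSE, sep = " ")
  invisible(path)
}

#' Assemble an LD reference from r2 records and a variant index
#'
#' Builds symmetric per-variant neighbor lists (compressed sparse rows)
#' including the self-pair at r2 = 1, with heterozygosities computed from the
#' index frequencies.  Neighbors are ordered deterministically by
#' (chromosome, position).
#'
#' @param records Data frame with columns `id_a`, `id_b`, `r2` (e.g. from
#'   [compute_ld_from_genotypes()] or [parse_plink_ld_text()]).
#' @param variants Data frame with columns `id`, `chr`, `bp`, `a1`, `a2`,
#'   `freq` (effect-allele frequency in the reference genotypes).
#' @return An object of class `ld_reference` with fields `variants`
#'   (augmented with `het`), `ptr` (0-based CSR offsets, length V+1),
#'   `nbr_idx` (1-based variant indices) and `nbr_r2`.
#' @export
build_reference <- function(records, variants) {
  stopifnot(all(c("id", "chr", "bp", "freq") %in% names(variants)))
  o <- order(variants$chr, variants$bp)
  variants <- variants[o, , drop = FALSE]
  rownames(variants) <- NULL
  V <- nrow(variants)
  idx <- seq_len(V)
  names(idx) <- variants$id
  unknown <- unique(c(setdiff(records$id_a, variants$id),
                      setdiff(records$id_b, variants$id)))
  if (length(unknown)) {
    stop("r2 records reference unknown variant id(s): ",
         paste(head(unknown, 10), collapse = ", "))
  }
  ia <- unname(idx[records$id_a])
  ib <- unname(idx[records$id_b])
  off <- !is.na(ia) & !is.na(ib) & ia != ib
  src <- c(idx, ia[off], ib[off])
  dst <- c(idx, ib[off], ia[off])
  r2 <- c(rep(1, V), records$r2[off], records$r2[off])
  # drop duplicate pairs (keep first occurrence)
  key <- paste(src, dst)
  dup <- duplicated(key)
  src <- src[!dup]; dst <- dst[!dup]; r2 <- r2[!dup]
  o2 <- order(src, dst)  # variants already (chr, bp)-sorted, so index order
  src <- src[o2]; dst <- dst[o2]; r2 <- r2[o2]
  ptr <- c(0L, cumsum(tabulate(src, nbins = V)))
  variants$het <- heterozygosity_from_freq(variants$freq)
  structure(list(variants = variants, ptr = as.integer(ptr),
                 nbr_idx = as.integer(dst), nbr_r2 = r2),
            class = "ld_reference")
}

#' @export
print.ld_reference <- function(x, ...) {
  V <- nrow(x$variants)
  cat(sprintf(
    "LD reference: %d variants, %.2f neighbors/variant (self included)\n",
    V, length(x$nbr_idx) / max(V, 1)))
  invisible(x)
}

#' Neighbor list of one variant
#'
#' @param reference An `ld_reference`.
#' @param id Variant id (character) or index (integer).
#' @return Data frame with neighbor `id`, `r2`, `het`.
#' @export
ld_neighbors <- function(reference, id) {
  j <- if (is.character(id)) match(id, reference$variants$id) else as.integer(id)
  if (is.na(j) || j < 1 || j > nrow(reference$variants)) {
    stop("unknown variant: ", id)
  }
  sel <- (reference$ptr[j] + 1L):reference$ptr[j + 1L]
  k <- reference$nbr_idx[sel]
  data.frame(id = reference$variants$id[k], r2 = reference$nbr_r2[sel],
             het = reference$variants$het[k], stringsAsFactors = FALSE)
}

#' Persist / load an LD reference container
#'
#' The neighbor structure is stored in a single binary container (RDS) with a
#' JSON sidecar (`<path>.json`) carrying the variant index and a versioned
#' header.
#'
#' @param reference An `ld_reference`.
#' @param path Path of the container file.
#' @return `save_reference()`: `path`, invisibly. `load_reference()`: the
#'   `ld_reference`.
#' @export
save_reference <- function(reference, path) {
  stopifnot(inherits(reference, "ld_reference"))
  saveRDS(reference, path)
  sidecar <- list(format = "trivarmix_ld_reference", version = 1L,
                  n_variants = nrow(reference$variants),
                  n_pairs = length(reference$nbr_idx),
                  variants = reference$variants)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_reference
#' @export
load_reference <- function(path) {
  ref <- readRDS(path)
  if (!inherits(ref, "ld_reference")) stop("not an LD reference container")
  ref
}
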