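# GWAS summary-statistics intake: flexible column mapping, allele
# harmonization against the LD reference, quality-control filters and the
# seeded random pruning + subsetting that defines an optimization template.

.SS_ALIASES <- list(
  id = c("SNP", "RSID"), chr = c("CHR"), bp = c("BP", "POS"),
  a1 = c("A1", "EA"), a2 = c("A2", "OA"), z = c("Z"), beta = c("BETA"),
  se = c("SE"), n = c("N"), freq = c("FRQ", "EAF"), info = c("INFO"))

#' Read a GWAS summary-statistics table
#'
#' Whitespace/tab-delimited text with a header.  Recognized columns
#' (case-insensitive): `SNP`/`RSID`, `CHR`, `BP`/`POS`, `A1`/`EA`, `A2`/`OA`,
#' `Z` (or `BETA` + `SE`, converted as `z = beta/se`), `N`, `FRQ`/`EAF`,
#' `INFO`.
#'
#' @param path File path.
#' @return Data frame with canonical columns `id`, `chr`, `bp`, `a1`, `a2`,
#'   `z`, `n` and, when present, `freq` and `info`.  Rows with missing `z`
#'   or `n` are dropped.
#' @export
read_sumstats <- function(path) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  up <- toupper(names(tab))
  pick <- function(field) {
    hit <- match(.SS_ALIASES[[field]], up)
    hit <- hit[!is.na(hit)]
    if (length(hit)) tab[[hit[1]]] else NULL
  }
  out <- data.frame(id = as.character(pick("id")), stringsAsFactors = FALSE)
  for (f in c("chr", "bp")) {
    v <- pick(f)
    if (!is.null(v)) out[[f]] <- as.numeric(v)
  }
  a1 <- pick("a1"); a2 <- pick("a2")
  if (is.null(a1) || is.null(a2)) {
    stop("sumstats file ", path, " lacks allele columns (A1/EA and A2/OA)")
  }
  out$a1 <- toupper(as.character(a1))
  out$a2 <- toupper(as.character(a2))
  z <- pick("z")
  if (is.null(z)) {
    beta <- pick("beta"); se <- pick("se")
    if (is.null(beta) || is.null(se)) {
      stop("sumstats file ", path, " has neither Z nor BETA+SE columns")
    }
    z <- as.numeric(beta) / as.numeric(se)
  }
  out$z <- as.numeric(z)
  nn <- pick("n")
  if (is.null(nn)) stop("sumstats file ", path, " lacks an N column")
  out$n <- as.numeric(nn)
  for (f in c("freq", "info")) {
    v <- pick(f)
    if (!is.null(v)) out[[f]] <- as.numeric(v)
  }
  if (anyDuplicated(out$id)) {
    stop(sum(duplicated(out$id)), " duplicate variant id(s) in ", path)
  }
  drop <- !is.finite(out$z) | !is.finite(out$n) | out$n <= 0
  if (any(drop)) {
    message(sum(drop), " row(s) with missing/invalid z or n dropped from ",
            path)
    out <- out[!drop, , drop = FALSE]
  }
  if (!is.null(out$freq) &&
      any(out$freq < 0 | out$freq > 1, na.rm = TRUE)) {
    stop("freq outside [0, 1] in ", path)
  }
  rownames(out) <- NULL
  out
}

.is_palindromic <- function(a1, a2) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(comp[a1]) & comp[a1] == a2
}

#' Harmonize three summary-statistics tables against an LD reference
#'
#' Inner join on variant id against the reference index; a study z-score is
#' sign-flipped when its effect allele equals the reference's other allele;
#' strand-ambiguous (A/T, C/G) variants are dropped with a logged count.
#' An unresolvable allele mismatch (neither match nor swap) is an error.
#'
#' @param tables List of three data frames from [read_sumstats()] (or paths,
#'   which are read first).
#' @param reference An `ld_reference` from [build_reference()].
#' @return Object of class `harmonized_sumstats`: list with `idx` (indices
#'   into the reference variant table), `z` and `n` (V x 3 matrices), `info`
#'   (V x 3 matrix or `NULL`), plus a `counts` attribute with per-step
#'   removal counts.
#' @export
harmonize_sumstats <- function(tables, reference) {
  if (length(tables) != 3L) stop("exactly 3 sumstats tables are required")
  tables <- lapply(tables, function(t) {
    if (is.character(t)) read_sumstats(t) else t
  })
  ref <- reference$variants
  counts <- list()
  ids <- ref$id
  for (s in 1:3) ids <- intersect(ids, tables[[s]]$id)
  n_shared <- length(ids)
  if (n_shared == 0L) stop("no shared variants across the three studies")
  ridx <- match(ids, ref$id)
  z <- matrix(NA_real_, n_shared, 3)
  nmat <- matrix(NA_real_, n_shared, 3)
  have_info <- all(vapply(tables, function(t) !is.null(t$info), TRUE))
  info <- if (have_info) matrix(NA_real_, n_shared, 3) else NULL
  drop_pal <- logical(n_shared)
  for (s in 1:3) {
    t <- tables[[s]]
    m <- match(ids, t$id)
    a1 <- t$a1[m]; a2 <- t$a2[m]
    pal <- .is_palindromic(a1, a2)
    drop_pal <- drop_pal | pal
    straight <- a1 == ref$a1[ridx] & a2 == ref$a2[ridx]
    swapped <- a1 == ref$a2[ridx] & a2 == ref$a1[ridx]
    mism <- !straight & !swapped & !pal
    if (any(mism)) {
      stop(sum(mism), " unresolvable allele mismatch(es) against the ",
           "reference in study ", s)
    }
    zz <- t$z[m]
    zz[swapped] <- -zz[swapped]
    z[, s] <- zz
    nmat[, s] <- t$n[m]
    if (have_info) info[, s] <- t$info[m]
  }
  counts$shared <- n_shared
  counts$palindromic_dropped <- sum(drop_pal)
  if (any(drop_pal)) {
    message(sum(drop_pal), " strand-ambiguous (A/T, C/G) variant(s) dropped")
  }
  keep <- !drop_pal
  structure(list(idx = ridx[keep], z = z[keep, , drop = FALSE],
                 n = nmat[keep, , drop = FALSE],
                 info = if (have_info) info[keep, , drop = FALSE] else NULL),
            counts = counts, class = "harmonized_sumstats")
}

#' Quality-control configuration
#'
#' Defaults follow the conventional analysis settings: MAF below 5% excluded
#' (MAF taken from the reference genotypes), INFO below 0.8 excluded when an
#' INFO column is present, |z| above 32 excluded, the MHC
#' (chr6:25,000,000-34,000,000, 1-based inclusive, hg19) excluded, random
#' pruning at r2 >= 0.8 and a random subset of 500,000 template variants,
#' all driven by one seeded pseudo-random stream.
#'
#' @param maf_thresh Minor-allele-frequency threshold.
#' @param info_thresh Imputation INFO threshold (ignored without INFO).
#' @param z_thresh Absolute z-score threshold.
#' @param exclude_regions Character vector of `chr:start-end` regions.
#' @param do_pruning Whether to randomly prune by LD.
#' @param r2_prune_thresh Pruning threshold: neighbors with r2 >= this are
#'   removed when a visited variant is kept.
#' @param n_random Size of the random template subset.
#' @param rand_prune_seed Seed(s) of the stream controlling both pruning and
#'   subsetting.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(maf_thresh = 0.05, info_thresh = 0.8, z_thresh = 32,
                      exclude_regions = "6:25000000-34000000",
                      do_pruning = TRUE, r2_prune_thresh = 0.8,
                      n_random = 500000, rand_prune_seed = 1L) {
  stopifnot(maf_thresh >= 0, info_thresh >= 0, z_thresh >= 0,
            r2_prune_thresh >= 0, n_random >= 1)
  structure(list(maf_thresh = maf_thresh, info_thresh = info_thresh,
                 z_thresh = z_thresh, exclude_regions = exclude_regions,
                 do_pruning = do_pruning, r2_prune_thresh = r2_prune_thresh,
                 n_random = n_random, rand_prune_seed = rand_prune_seed),
            class = "qc_config")
}

# "chr:start-end" -> list(chr, start, end); bounds are 1-based inclusive
.parse_region <- function(s) {
  m <- regmatches(s, regexec("^([0-9XY]+):([0-9]+)[-–]([0-9]+)$", s))[[1]]
  if (length(m) != 4L) stop("malformed region '", s, "' (want chr:start-end)")
  list(chr = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}

#' Quality-control filter on harmonized summary statistics
#'
#' Drops variants with reference MAF below `maf_thresh`, INFO below
#' `info_thresh` in any study (skipped when no INFO columns were present),
#' `|z| > z_thresh` in any study, and variants inside any excluded region.
#' The filter is idempotent and logs per-filter removal counts.
#'
#' @param harmonized A `harmonized_sumstats` object.
#' @param config A [qc_config()].
#' @param reference The `ld_reference` the data were harmonized against.
#' @return A filtered `harmonized_sumstats` (same structure, fewer rows),
#'   with a `qc_counts` attribute.
#' @export
qc_filter <- function(harmonized, config, reference) {
  stopifnot(inherits(harmonized, "harmonized_sumstats"),
            inherits(config, "qc_config"))
  ref <- reference$variants
  V <- length(harmonized$idx)
  keep <- rep(TRUE, V)
  counts <- list()
  maf <- pmin(ref$freq[harmonized$idx], 1 - ref$freq[harmonized$idx])
  bad <- maf < config$maf_thresh
  counts$maf <- sum(bad & keep); keep <- keep & !bad
  if (!is.null(harmonized$info)) {
    bad <- apply(harmonized$info < config$info_thresh, 1, any)
    counts$info <- sum(bad & keep); keep <- keep & !bad
  } else {
    counts$info <- 0L  # no INFO columns: filter ignored
  }
  bad <- apply(abs(harmonized$z) > config$z_thresh, 1, any)
  counts$z <- sum(bad & keep); keep <- keep & !bad
  in_region <- rep(FALSE, V)
  for (rg in config$exclude_regions) {
    r <- .parse_region(rg)
    in_region <- in_region |
      (as.character(ref$chr[harmonized$idx]) == r$chr &
         ref$bp[harmonized$idx] >= r$start & ref$bp[harmonized$idx] <= r$end)
  }
  counts$region <- sum(in_region & keep); keep <- keep & !in_region
  message(sprintf(
    "QC: %d in, %d removed (maf %d, info %d, z %d, region %d), %d out",
    V, sum(!keep), counts$maf, counts$info, counts$z, counts$region,
    sum(keep)))
  out <- list(idx = harmonized$idx[keep],
              z = harmonized$z[keep, , drop = FALSE],
              n = harmonized$n[keep, , drop = FALSE],
              info = if (is.null(harmonized$info)) NULL else
                harmonized$info[keep, , drop = FALSE])
  structure(out, counts = attr(harmonized, "counts"), qc_counts = counts,
            class = "harmonized_sumstats")
}

# Greedy pruning with an explicit visiting order: visit variants in `order`;
# keep the visited variant unless already marked removed, and mark all its
# reference neighbors at r2 >= thresh removed.  Exposed internally so the
# rule can be unit-tested deterministically.
.prune_visit <- function(order, ref_idx, reference, r2_thresh) {
  pos <- integer(nrow(reference$variants))  # reference index -> template slot
  pos[ref_idx] <- seq_along(ref_idx)
  removed <- logical(length(ref_idx))
  kept <- logical(length(ref_idx))
  for (slot in order) {
    if (removed[slot]) next
    kept[slot] <- TRUE
    j <- ref_idx[slot]
    sel <- (reference$ptr[j] + 1L):reference$ptr[j + 1L]
    hit <- reference$nbr_r2[sel] >= r2_thresh
    nb <- pos[reference$nbr_idx[sel][hit]]
    nb <- nb[nb > 0L & nb != slot]
    removed[nb] <- TRUE
  }
  kept
}

#' Random pruning and subsetting of the optimization template
#'
#' Visits the QC-surviving variants in a seed-determined random order,
#' keeping each visited variant unless it was already removed and removing
#' all its reference neighbors with `r2 >= r2_prune_thresh`; afterwards draws
#' `min(n_random, remaining)` variants uniformly without replacement from the
#' survivors, continuing the same pseudo-random stream.  Fully reproducible
#' given `rand_prune_seed`.
#'
#' @param harmonized A QC-filtered `harmonized_sumstats`.
#' @param reference The `ld_reference`.
#' @param config A [qc_config()]; `rand_prune_seed` must be a single seed
#'   here (see [multi_run()] for seed lists).
#' @return Integer vector of reference variant indices forming the template,
#'   sorted by (chromosome, position).
#' @export
prune_and_subset <- function(harmonized, reference, config) {
  stopifnot(inherits(harmonized, "harmonized_sumstats"))
  seed <- config$rand_prune_seed[1]
  V <- length(harmonized$idx)
  if (V == 0L) return(integer(0))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  if (isTRUE(config$do_pruning)) {
    visit <- sample.int(V)
    kept <- .prune_visit(visit, harmonized$idx, reference,
                         config$r2_prune_thresh)
  } else {
    kept <- rep(TRUE, V)
  }
  surv <- which(kept)
  n_take <- min(config$n_random, length(surv))
  template <- sort(harmonized$idx[sample(surv, n_take)])
  message(sprintf(
    "template: %d variants after pruning, %d randomly selected (seed %d)",
    length(surv), n_take, seed))
  template
}
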