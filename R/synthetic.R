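# Synthetic Hi-C data with known ground truth: block-diagonal-by-chromosome
# maps with power-law distance decay, per-bin visibilities, a constant
# inter-chromosomal background, planted proximity modules, Poisson noise,
# and expression profiles whose ON genes are enriched in planted modules.

#' Simulate a balanced contact map with known truth
#'
#' Expected intensity
#' \eqn{\lambda_{ij} = depth \cdot v_i v_j \cdot [g(|i-j|) \textrm{ intra};
#' c_0 \textrm{ inter}] \cdot m_{ij}}, where
#' \eqn{g(d) = (d+1)^{-\gamma} + 10^{-3} g(1)} (the additive floor keeps
#' long-range intra expectations estimable), v are per-bin multiplicative
#' visibilities (log-normal, mean 1), and \eqn{m_{ij}} is the boost of a
#' planted module containing both bins (1 elsewhere). The emitted matrix is
#' \eqn{\lambda} itself (\code{noise = "none"}) or symmetric Poisson draws
#' with mean \eqn{\lambda}.
#'
#' @param n_chrom number of chromosomes (>= 2 unless intra-only use).
#' @param bins_per_chrom bins per chromosome (>= 2).
#' @param gamma power-law decay exponent.
#' @param c0 inter-chromosomal background (same units as g).
#' @param visibility_spread SD of log visibilities (0 = flat).
#' @param modules list of planted modules, each
#'   \code{list(bins = <global 1-based bin indices>, boost = m)}; a bin pair
#'   inside one module gets its boost; membership in two modules with
#'   conflicting boosts is an error.
#' @param depth sequencing-depth scale (expected counts at d = 1 are about
#'   \code{depth * g(1)}).
#' @param noise \code{"poisson"} or \code{"none"}.
#' @param seed integer seed.
#' @param bin_size bp per bin (cosmetic; coordinates only).
#' @return list with \code{cmap} (a \code{contact_map}) and \code{truth}
#'   (class \code{synthetic_truth}: v, gamma, floor, c0, depth, modules,
#'   binning, seed).
#' @export
simulate_contact_map <- function(n_chrom = 5, bins_per_chrom = 200,
                                 gamma = 1, c0 = 0.01,
                                 visibility_spread = 0.3,
                                 modules = list(), depth = 300,
                                 noise = c("poisson", "none"),
                                 seed = NULL, bin_size = 40000) {
  noise <- match.arg(noise)
  stopifnot(n_chrom >= 1, bins_per_chrom >= 2, depth > 0, gamma > 0, c0 >= 0)
  if (!is.null(seed)) set.seed(seed)
  binning <- genome_binning(paste0("chr", seq_len(n_chrom)),
                            rep(bins_per_chrom * bin_size, n_chrom),
                            bin_size)
  N <- binning$n_bins
  v <- exp(stats::rnorm(N, 0, visibility_spread))
  v <- v / mean(v)
  g1 <- 2^(-gamma)
  floor_g <- 1e-3 * g1
  D <- abs(outer(seq_len(N), seq_len(N), "-"))
  same <- outer(binning$bin_chrom, binning$bin_chrom, "==")
  base <- matrix(c0, N, N)
  base[same] <- (D[same] + 1)^(-gamma) + floor_g
  boost <- matrix(1, N, N)
  for (mod in modules) {
    stopifnot(!is.null(mod$bins), !is.null(mod$boost), mod$boost >= 1)
    b <- as.integer(mod$bins)
    if (any(b < 1 | b > N)) stop("module bin index out of range")
    cur <- boost[b, b]
    if (any(cur != 1 & cur != mod$boost))
      stop("overlapping modules with conflicting boosts")
    boost[b, b] <- mod$boost
  }
  lambda <- depth * tcrossprod(v) * base * boost
  if (noise == "none") {
    m <- lambda
  } else {
    m <- matrix(0, N, N)
    ut <- upper.tri(lambda, diag = TRUE)
    m[ut] <- stats::rpois(sum(ut), lambda[ut])
    m <- m + t(m)
    diag(m) <- diag(m) / 2
  }
  truth <- structure(list(v = v, gamma = gamma, g_floor = floor_g, c0 = c0,
                          depth = depth, modules = modules,
                          binning = binning, noise = noise, seed = seed),
                     class = "synthetic_truth")
  list(cmap = contact_map(m, binning), truth = truth)
}

#' True decay curve of a synthetic map
#'
#' @param truth a \code{synthetic_truth}.
#' @param d distances in bin units.
#' @return \eqn{g(d) = (d+1)^{-\gamma} + 10^{-3} g(1)}.
#' @export
true_decay <- function(truth, d) {
  (d + 1)^(-truth$gamma) + truth$g_floor
}

#' Simulate genes, expression, and domain annotations on a synthetic map
#'
#' Places one gene per selected bin (module bins first, the rest uniformly
#' at random) and draws an ON gene set by weighted sampling without
#' replacement: weight \code{module_on_enrichment} inside planted modules,
#' \code{compartment_on_enrichment} elsewhere in the A compartment, 1 in B.
#' Log2 expression comes from two Gaussian components (ON high, OFF low;
#' linear-scale values are 2^log2) and a fraction of OFF genes is zeroed.
#' TADs are consecutive-bin blocks. Compartments mimic the active-minority
#' structure of real chromatin: every fourth segment of
#' \code{compartment_bins} bins is A (the rest B), and any segment holding
#' a planted-module bin is forced to A, so A covers roughly a quarter to a
#' third of each chromosome and carries the transcribed genes.
#'
#' @param truth a \code{synthetic_truth} from [simulate_contact_map()].
#' @param genes_per_chrom genes per chromosome (<= bins per chromosome).
#' @param on_fraction fraction of genes ON (0 < f < 1).
#' @param module_on_enrichment ON-sampling weight multiplier inside
#'   modules (>= 1; 1 = uniform).
#' @param compartment_on_enrichment ON-sampling weight in the A compartment
#'   outside modules (>= 1; set to 1 together with
#'   \code{module_on_enrichment = 1} for a fully uniform ON set).
#' @param expr_means log2 means, named \code{off} and \code{on}.
#' @param expr_sd log2 SD of both components.
#' @param zero_fraction fraction of OFF genes set to exactly zero.
#' @param tad_bins TAD width in bins.
#' @param compartment_bins compartment segment width in bins.
#' @param seed integer seed.
#' @return list: \code{genes} (\code{gene_table}), \code{expr}
#'   (\code{expression_profile}), \code{tads}, \code{compartments}
#'   (\code{domain_annotation}s), \code{on_genes} (ids),
#'   \code{module_genes} (list of id vectors per planted module),
#'   \code{gene_bin} (named bin index per gene).
#' @export
simulate_genes_and_expression <- function(truth, genes_per_chrom = 100,
                                          on_fraction = 0.3,
                                          module_on_enrichment = 1,
                                          compartment_on_enrichment = module_on_enrichment,
                                          expr_means = c(off = 0, on = 5),
                                          expr_sd = 1, zero_fraction = 0.05,
                                          tad_bins = 10,
                                          compartment_bins = 25,
                                          seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"),
            on_fraction > 0, on_fraction < 1, module_on_enrichment >= 1,
            compartment_on_enrichment >= 1)
  if (!is.null(seed)) set.seed(seed)
  b <- truth$binning
  module_bins <- sort(unique(unlist(lapply(truth$modules, `[[`, "bins"))))
  gene_bins <- integer(0)
  for (ch in b$chrom_names) {
    nb <- b$bins_per_chrom[[ch]]
    stopifnot(genes_per_chrom <= nb)
    all_ch <- b$chrom_offset[[ch]] + seq_len(nb)
    must <- intersect(all_ch, module_bins)
    rest <- setdiff(all_ch, must)
    extra <- sort(sample(rest, max(0, genes_per_chrom - length(must))))
    gene_bins <- c(gene_bins, sort(c(must, extra))[seq_len(genes_per_chrom)])
  }
  G <- length(gene_bins)
  ids <- sprintf("g%04d", seq_len(G))
  start <- b$bin_start[gene_bins]
  genes <- gene_table(data.frame(
    gene_id = ids, chrom = b$bin_chrom[gene_bins],
    start = start, end = start + b$bin_size, strand = "*",
    stringsAsFactors = FALSE))
  tads <- make_blocks(b, tad_bins, function(ch, i, s, e)
    sprintf("tad_%s_%03d", ch, i))
  # active minority compartment: every 4th segment is A, rest B ...
  comp <- make_blocks(b, compartment_bins, function(ch, i, s, e)
    if (i %% 4 == 1) "A" else "B")
  # ... and segments containing planted-module bins are forced to A
  if (length(module_bins)) {
    mb_chrom <- b$bin_chrom[module_bins]
    mb_start <- b$bin_start[module_bins]
    for (r in seq_len(nrow(comp))) {
      hit <- mb_chrom == comp$chrom[r] &
        mb_start >= comp$start[r] & mb_start < comp$end[r]
      if (any(hit)) comp$label[r] <- "A"
    }
  }
  compartments <- domain_annotation(comp, "compartment")
  in_module <- gene_bins %in% module_bins
  in_A <- !is.na(domain_of(genes, compartments)) &
    domain_of(genes, compartments) == "A"
  w <- ifelse(in_module, module_on_enrichment,
              ifelse(in_A, compartment_on_enrichment, 1))
  n_on <- round(on_fraction * G)
  on_idx <- sample.int(G, n_on, prob = w)
  lvals <- stats::rnorm(G, expr_means[["off"]], expr_sd)
  lvals[on_idx] <- stats::rnorm(n_on, expr_means[["on"]], expr_sd)
  values <- 2^lvals
  off_idx <- setdiff(seq_len(G), on_idx)
  n_zero <- round(zero_fraction * length(off_idx))
  if (n_zero > 0) values[sample(off_idx, n_zero)] <- 0
  expr <- expression_profile(stats::setNames(values, ids))
  module_genes <- lapply(truth$modules, function(mod)
    ids[gene_bins %in% mod$bins])
  list(genes = genes, expr = expr,
       tads = domain_annotation(tads, "tad"),
       compartments = compartments,
       on_genes = ids[sort(on_idx)],
       module_genes = module_genes,
       gene_bin = stats::setNames(gene_bins, ids))
}

make_blocks <- function(binning, width_bins, label_fun) {
  out <- list()
  for (ch in binning$chrom_names) {
    nb <- binning$bins_per_chrom[[ch]]
    starts <- seq(0, nb - 1, by = width_bins)
    ends <- pmin(starts + width_bins, nb)
    out[[ch]] <- data.frame(
      chrom = ch,
      start = starts * binning$bin_size,
      end = ends * binning$bin_size,
      label = vapply(seq_along(starts), function(i)
        label_fun(ch, i, starts[i], ends[i]), character(1)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' One-call synthetic study with planted signal
#'
#' Convenience wrapper that simulates a complete study under the package's
#' standard synthetic conditions: a contact map with planted intra- and
#' inter-chromosomal proximity modules, genes (one per bin), an ON/OFF
#' expression profile enriched in the modules, and TAD/compartment tracks.
#' Two presets are provided: \code{"small"} (5 chromosomes x 200 bins, 500
#' genes) and \code{"tiny"} (3 chromosomes x 60 bins, 120 genes, for fast
#' repeated runs).
#'
#' @param preset \code{"small"} or \code{"tiny"}.
#' @param seed integer seed driving every random draw.
#' @param module_boost contact boost m of planted intra modules.
#' @param inter_boost boost of the condition-specific (differential)
#'   inter-chromosomal module; set to 1 for a matched control condition
#'   (gene placement stays identical, and a second, shared inter module is
#'   planted in every condition as common background structure).
#' @param on_enrichment ON-sampling weight inside modules.
#' @param noise \code{"poisson"} or \code{"none"}.
#' @param depth sequencing-depth scale.
#' @return list: everything from [simulate_contact_map()] and
#'   [simulate_genes_and_expression()], plus \code{modules} (the
#'   differential inter module listed last) and \code{inter_chroms} (the
#'   chromosome pair carrying it).
#' @export
simulate_cgp_study <- function(preset = c("small", "tiny"), seed = 1,
                               module_boost = 3, inter_boost = module_boost,
                               on_enrichment = 10,
                               noise = c("poisson", "none"), depth = 300) {
  preset <- match.arg(preset)
  noise <- match.arg(noise)
  p <- if (preset == "small") {
    list(n_chrom = 5, bins = 200, gpc = 100,
         intra = list(chr1 = 21:30, chr2 = 41:50, chr3 = 101:110,
                      chr4 = 151:160),
         inter_shared = list(chr4 = 101:110, chr5 = 51:60),
         inter = list(chr1 = 61:80, chr2 = 121:140))
  } else {
    list(n_chrom = 3, bins = 60, gpc = 40,
         intra = list(chr1 = 11:18, chr2 = 21:28),
         inter_shared = list(chr1 = 51:56, chr2 = 51:56),
         inter = list(chr1 = 21:40, chr3 = 21:40))
  }
  off <- function(ch) (match(ch, paste0("chr", seq_len(p$n_chrom))) - 1) * p$bins
  globalize <- function(groups) unlist(lapply(names(groups), function(ch)
    off(ch) + groups[[ch]]), use.names = FALSE)
  modules <- lapply(names(p$intra), function(ch)
    list(bins = off(ch) + p$intra[[ch]], boost = module_boost))
  # one inter-chromosomal module common to every condition (background
  # inter structure, as two related cell types would share) and one whose
  # boost is condition-specific (the differential module, listed last)
  modules <- c(modules,
               list(list(bins = globalize(p$inter_shared),
                         boost = module_boost)),
               list(list(bins = globalize(p$inter), boost = inter_boost)))
  sim <- simulate_contact_map(n_chrom = p$n_chrom, bins_per_chrom = p$bins,
                              modules = modules, depth = depth,
                              noise = noise, seed = seed)
  ge <- simulate_genes_and_expression(sim$truth, genes_per_chrom = p$gpc,
                                      module_on_enrichment = on_enrichment,
                                      compartment_on_enrichment =
                                        max(1, on_enrichment / 2),
                                      seed = seed + 1000L)
  c(sim, ge, list(modules = modules, inter_chroms = names(p$inter)))
}
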