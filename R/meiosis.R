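# Meiosis and single seed descent on a genetic map.
#
# Crossovers follow the no-interference count-location model: per
# chromosome the crossover count is Poisson with mean equal to the map
# length in Morgans and positions are uniform on the map. At the marker
# loci this process is Markov along the chromosome with switch probability
# between adjacent markers given by Haldane's mapping function
# r = (1 - exp(-2d))/2, which is what the vectorized bulk sampler uses.

# Precompute per-chromosome column indices and adjacent recombination
# fractions for a map aligned to a marker panel.
.map_layout <- function(map, marker_ids) {
  validate_genetic_map(map)
  if (!identical(map$marker_id, marker_ids)) {
    missing <- setdiff(marker_ids, map$marker_id)
    if (length(missing)) {
      stop("marker(s) absent from the genetic map: ",
           paste(utils::head(missing, 5L), collapse = ", "),
           if (length(missing) > 5L) ", ..." else "")
    }
    stop("genotype marker order must match genetic map order; use align_to_map()")
  }
  lapply(split(seq_along(marker_ids), map$chromosome), function(cols) {
    pos <- map$position_cM[cols]
    d <- diff(pos) / 100 # Morgans
    list(cols = cols, pos = pos,
         r = (1 - exp(-2 * d)) / 2,
         length_M = (max(pos) - min(pos)) / 100,
         lo = min(pos), hi = max(pos))
  })
}

#' Split a parental genotype row into two phased haplotypes
#'
#' Homozygous calls split deterministically (0 -> 0/0, 2 -> 1/1, in
#' counted-allele dosage). Heterozygous calls are phased by a seeded coin
#' flip per chromosome: within a chromosome all heterozygous sites share
#' one phase draw.
#'
#' @param parent Named vector of calls in \{0,1,2\} (no missing), in map
#'   order.
#' @param map Genetic map covering the markers.
#' @param seed Optional integer seed for the phasing coins.
#' @return List of two 0/1 haplotype vectors summing to the parent calls.
#' @export
founder_haplotypes <- function(parent, map, seed = NULL) {
  if (anyNA(parent)) stop("parental genotype has missing calls: impute first")
  if (!all(parent %in% c(0, 1, 2))) stop("parental calls must be in {0,1,2}")
  layout <- .map_layout(map, names(parent))
  h1 <- h2 <- as.integer(parent == 2)
  with_seed(seed, {
    for (ch in layout) {
      het <- ch$cols[parent[ch$cols] == 1]
      if (length(het)) {
        if (runif(1) < 0.5) {
          h1[het] <- 1L; h2[het] <- 0L
        } else {
          h1[het] <- 0L; h2[het] <- 1L
        }
      }
    }
  })
  names(h1) <- names(h2) <- names(parent)
  list(h1, h2)
}

#' Simulate one gamete from a pair of haplotypes
#'
#' Literal count-location implementation: per chromosome the number of
#' crossovers is Poisson with mean equal to the chromosome map length in
#' Morgans, crossover positions are uniform on the map, and the source
#' haplotype alternates at each crossover starting from a fair coin.
#' Chromosomes assort independently.
#'
#' @param h1,h2 Haplotype vectors (same markers, map order).
#' @param map Genetic map.
#' @param seed Optional integer seed.
#' @return A haplotype vector.
#' @export
simulate_gamete <- function(h1, h2, map, seed = NULL) {
  stopifnot(length(h1) == length(h2))
  layout <- .map_layout(map, names(h1))
  out <- h1
  with_seed(seed, {
    for (ch in layout) {
      k <- rpois(1L, ch$length_M)
      xo <- if (k > 0L) sort(runif(k, ch$lo, ch$hi)) else numeric(0)
      src <- (as.integer(runif(1) < 0.5) + findInterval(ch$pos, xo)) %% 2L
      take2 <- ch$cols[src == 1L]
      out[take2] <- h2[take2]
    }
  })
  out
}

# Vectorized gametes: one independent meiosis per row of H1/H2.
# Uses the Markov switch representation of the no-interference model.
.gametes_bulk <- function(H1, H2, layout) {
  n <- nrow(H1)
  out <- H1
  for (ch in layout) {
    cols <- ch$cols
    cur <- runif(n) < 0.5
    pick2 <- cur
    if (length(cols) > 1L) {
      src <- matrix(FALSE, n, length(cols))
      src[, 1L] <- cur
      for (j in 2L:length(cols)) {
        cur <- xor(cur, runif(n) < ch$r[j - 1L])
        src[, j] <- cur
      }
      block <- H1[, cols, drop = FALSE]
      b2 <- H2[, cols, drop = FALSE]
      block[src] <- b2[src]
      out[, cols] <- block
    } else {
      out[pick2, cols] <- H2[pick2, cols]
    }
  }
  out
}

#' Simulate many independent gametes from one plant
#'
#' Vectorized version of [simulate_gamete()]: `n` independent meioses of
#' the plant with haplotypes `h1`/`h2`. Equivalent in distribution at the
#' marker loci to the count-location sampler.
#'
#' @param h1,h2 Haplotype vectors.
#' @param map Genetic map.
#' @param n Number of gametes.
#' @param seed Optional integer seed.
#' @return `n` x markers matrix of haplotypes.
#' @export
simulate_gametes <- function(h1, h2, map, n, seed = NULL) {
  stopifnot(n >= 1, length(h1) == length(h2))
  layout <- .map_layout(map, names(h1))
  H1 <- matrix(rep(as.integer(h1), each = n), n, length(h1))
  H2 <- matrix(rep(as.integer(h2), each = n), n, length(h2))
  colnames(H1) <- colnames(H2) <- names(h1)
  with_seed(seed, .gametes_bulk(H1, H2, layout))
}

#' Simulate F5-derived RIL progeny of a cross by single seed descent
#'
#' Starting from the two parents' phased haplotypes, each progeny descends
#' from its own meiotic events: an F1 is formed from one gamete of each
#' parent, then advanced by selfing (two independent gametes of the same
#' plant per generation, single seed descent) until the requested
#' generation; the default F5 needs four selfing rounds after the F1.
#' Residual heterozygosity is retained (about 1/16 per originally
#' segregating locus at F5), not forced to fixation.
#'
#' @param p1,p2 Named parental call vectors in \{0,1,2\} on the mapped
#'   panel (no missing calls), or single rows of a genotype matrix.
#' @param map Genetic map in the parents' marker order.
#' @param n Number of progeny (default 500, the scale used to emulate
#'   100-300 progeny rows per cross).
#' @param final_generation Filial generation to stop at (default 5).
#' @param seed Optional integer seed; identical inputs and seed give a
#'   bit-identical progeny set.
#' @param cross_id Optional label for the progeny set.
#' @return Object of class `progeny_set`: list with `cross` (parent ids),
#'   `geno` (`n` x markers call matrix), `generation`, `n`, `seed`.
#' @export
simulate_ril_progeny <- function(p1, p2, map, n = 500, final_generation = 5,
                                 seed = NULL, cross_id = NULL) {
  if (is.matrix(p1)) p1 <- p1[1L, ]
  if (is.matrix(p2)) p2 <- p2[1L, ]
  if (n <= 0) stop("n must be positive")
  if (final_generation < 2) stop("final_generation must be >= 2")
  if (!identical(names(p1), names(p2))) stop("parents must share the marker panel")
  layout <- .map_layout(map, names(p1))
  with_seed(seed, {
    hp1 <- founder_haplotypes(p1, map)
    hp2 <- founder_haplotypes(p2, map)
    expand <- function(h) matrix(rep(as.integer(h), each = n), n, length(h))
    # one F1 gamete from each parent per progeny (separate meioses)
    H1 <- .gametes_bulk(expand(hp1[[1L]]), expand(hp1[[2L]]), layout)
    H2 <- .gametes_bulk(expand(hp2[[1L]]), expand(hp2[[2L]]), layout)
    for (s in seq_len(final_generation - 1L)) {
      N1 <- .gametes_bulk(H1, H2, layout)
      N2 <- .gametes_bulk(H1, H2, layout)
      H1 <- N1
      H2 <- N2
    }
    geno <- H1 + H2
    colnames(geno) <- names(p1)
    if (is.null(cross_id)) cross_id <- "cross"
    rownames(geno) <- sprintf("%s_RIL%04d", cross_id, seq_len(n))
    structure(list(cross = cross_id,
                   geno = geno,
                   generation = paste0("F", final_generation),
                   n = n, seed = seed),
              class = "progeny_set")
  })
}

#' @export
print.progeny_set <- function(x, ...) {
  cat(sprintf("Simulated %s-derived RIL progeny: %d individuals x %d markers\n",
              x$generation, nrow(x$geno), ncol(x$geno)))
  invisible(x)
}
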