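#' Aggregate barcoded observations into a barcode-by-SNP count matrix
#'
#' Barcodes observing fewer than two distinct SNPs carry no linkage
#' information and are dropped.
#'
#' @param reads a \code{barcoded_read_set} (or a compatible data.frame
#'   with columns \code{barcode}, \code{snp}, \code{allele}).
#' @return a \code{barcode_matrix}: a data.table with one row per
#'   retained (barcode, SNP) pair and columns \code{ref_n},
#'   \code{alt_n}.
#' @export
build_barcode_matrix <- function(reads) {
  obs <- if (inherits(reads, "barcoded_read_set")) reads$observations else reads
  stopifnot(all(c("barcode", "snp", "allele") %in% names(obs)))
  dt <- data.table::as.data.table(obs)
  m <- dt[, list(ref_n = sum(allele == 0L), alt_n = sum(allele == 1L)),
          by = c("barcode", "snp")]
  m[, n_snp_bc := .N, by = "barcode"]
  m <- m[n_snp_bc >= 2L]
  m[, n_snp_bc := NULL]
  data.table::setkeyv(m, c("barcode", "snp"))
  n_snps <- if (inherits(reads, "barcoded_read_set")) length(reads$snp_pos) else
    max(obs$snp, 0L)
  data.table::setattr(m, "n_snps", as.integer(n_snps))
  data.table::setattr(m, "class", c("barcode_matrix", class(data.table::data.table())))
  m[]
}

# Per-barcode majority allele call at each SNP; ties are discarded.
barcode_calls <- function(matrix) {
  calls <- matrix[ref_n != alt_n,
                  list(barcode = barcode, snp = snp,
                       call = as.integer(alt_n > ref_n))]
  data.table::setorderv(calls, c("barcode", "snp"))
  calls
}

#' Build the pairwise phase-support graph
#'
#' Within each barcode the majority allele is taken at every observed
#' SNP (ties discarded for that SNP/barcode); every pair of
#' majority-called SNPs in one barcode then votes \emph{cis} (same
#' allele class at both, i.e. ref/ref or alt/alt) or \emph{trans}
#' (opposite) on the corresponding edge.
#'
#' @param matrix a \code{barcode_matrix}.
#' @return a \code{phase_graph}: data.table with columns \code{i},
#'   \code{j} (SNP indices, \code{i < j}), \code{cis}, \code{trans}.
#' @export
build_phase_graph <- function(matrix) {
  stopifnot(inherits(matrix, "barcode_matrix"))
  calls <- barcode_calls(matrix)
  grp <- split(seq_len(nrow(calls)), calls$barcode)
  snp <- calls$snp
  call <- calls$call
  pieces <- lapply(grp, function(ix) {
    k <- length(ix)
    if (k < 2L) return(NULL)
    i1 <- rep.int(seq_len(k - 1L), (k - 1L):1L)
    i2 <- sequence((k - 1L):1L, from = 2:k)
    list(snp[ix][i1], snp[ix][i2], call[ix][i1] == call[ix][i2])
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (!length(pieces)) {
    g <- data.table::data.table(i = integer(), j = integer(),
                                cis = integer(), trans = integer())
  } else {
    pairs <- data.table::data.table(
      i = unlist(lapply(pieces, `[[`, 1L), use.names = FALSE),
      j = unlist(lapply(pieces, `[[`, 2L), use.names = FALSE),
      same = unlist(lapply(pieces, `[[`, 3L), use.names = FALSE))
    g <- pairs[, list(cis = sum(same), trans = sum(!same)), by = c("i", "j")]
    data.table::setorderv(g, c("i", "j"))
  }
  data.table::setattr(g, "n_snps", attr(matrix, "n_snps"))
  data.table::setattr(g, "class", c("phase_graph", class(data.table::data.table())))
  g[]
}

# Kruskal maximum-support spanning forest with deterministic tie-breaks.
# edges: data.table with i, j, support (+ any payload); returns logical
# vector marking tree edges, and the union-find parent vector.
.kruskal <- function(i, j, support, n_nodes) {
  ord <- order(-support, i, j)
  parent <- seq_len(n_nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  tree <- logical(length(i))
  for (e in ord) {
    ri <- find(i[e]); rj <- find(j[e])
    if (ri != rj) {
      parent[ri] <- rj
      tree[e] <- TRUE
    }
  }
  root <- vapply(seq_len(n_nodes), find, 1L)
  list(tree = tree, root = root)
}

# Orient nodes over a spanning forest: flip across trans edges.
# Returns 0/1 orientation (NA for untouched nodes).
.orient_forest <- function(i, j, trans, n_nodes, roots) {
  adj <- vector("list", n_nodes)
  for (e in seq_along(i)) {
    adj[[i[e]]] <- c(adj[[i[e]]], list(c(j[e], trans[e])))
    adj[[j[e]]] <- c(adj[[j[e]]], list(c(i[e], trans[e])))
  }
  r <- rep(NA_integer_, n_nodes)
  for (s in roots) {
    if (!is.na(r[s])) next
    r[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (nb in adj[[v]]) {
        w <- nb[1L]
        if (is.na(r[w])) {
          r[w] <- if (nb[2L]) 1L - r[v] else r[v]
          queue <- c(queue, w)
        }
      }
    }
  }
  r
}

#' Call phase blocks from the support graph
#'
#' Edges are kept iff \code{max(cis, trans) >= min_support} and
#' \code{max/(cis + trans) >= min_ratio}; connected components of kept
#' edges become blocks. Relative phases are assigned by traversing a
#' maximum-support spanning tree (cis = same strand, trans = opposite;
#' ties broken by lower SNP index), and kept non-tree edges that
#' contradict the assignment are counted as conflicts. A block whose
#' conflicts exceed 5\% of its non-tree edges is flagged low-confidence.
#'
#' @param graph a \code{phase_graph}.
#' @param min_support minimum vote count on the winning orientation
#'   (default 2, so a single chimeric gem cannot set an edge).
#' @param min_ratio minimum winning-orientation share, in (0.5, 1].
#' @param positions optional SNP positions (bp) used to compute block
#'   spans.
#' @return a \code{phase_blocks} object: list of blocks, each with
#'   \code{snps}, \code{phase01} (allele01 on block strand 0),
#'   \code{span_bp}, \code{conflicts}, \code{n_nontree} and
#'   \code{low_confidence}.
#' @export
call_phase_blocks <- function(graph, min_support = 2L, min_ratio = 0.75,
                              positions = NULL) {
  stopifnot(inherits(graph, "phase_graph"))
  if (min_support < 1L) stop_hapdose("call_phase_blocks: min_support must be >= 1")
  if (min_ratio <= 0.5 || min_ratio > 1) {
    stop_hapdose("call_phase_blocks: min_ratio must lie in (0.5, 1]")
  }
  n_snps <- attr(graph, "n_snps")
  win <- pmax(graph$cis, graph$trans)
  tot <- graph$cis + graph$trans
  keep <- which(win >= min_support & win / tot >= min_ratio)
  blocks <- list()
  r <- rep(NA_integer_, n_snps)
  if (length(keep)) {
    ei <- graph$i[keep]; ej <- graph$j[keep]
    esup <- win[keep]
    ecis <- graph$cis[keep]; etrans_n <- graph$trans[keep]
    etrans <- etrans_n > ecis
    kr <- .kruskal(ei, ej, esup, n_snps)
    tr <- kr$tree
    r <- .orient_forest(ei[tr], ej[tr], etrans[tr], n_snps,
                        roots = sort(unique(c(ei, ej))))
    comp <- kr$root
    members <- split(sort(unique(c(ei, ej))),
                     comp[sort(unique(c(ei, ej)))])
    ord <- order(vapply(members, min, 1L))
    members <- members[ord]
    blocks <- lapply(members, function(snps) {
      in_blk <- which(ei %in% snps) # kept edges live within one component
      k <- length(snps)
      phase <- r[snps]
      if (k <= 12L && length(in_blk)) {
        # small blocks are solved exactly: enumerate every relative
        # phasing (lowest SNP fixed to strand 0) and take the maximum
        # agreement with the edge votes; ties resolve to the lowest
        # enumeration index for determinism
        bi <- match(ei[in_blk], snps)
        bj <- match(ej[in_blk], snps)
        cis_w <- ecis[in_blk]; trans_w <- etrans_n[in_blk]
        best <- -Inf; best_phase <- phase
        for (mask in 0:(2^(k - 1L) - 1L)) {
          cand <- c(0L, as.integer(intToBits(mask))[seq_len(k - 1L)])
          sc <- sum(ifelse(cand[bi] == cand[bj], cis_w, trans_w))
          if (sc > best) {
            best <- sc
            best_phase <- cand
          }
        }
        phase <- best_phase
      }
      # conflicts: kept edges whose majority orientation the final
      # assignment violates (always non-tree edges for large blocks)
      pmap <- rep(NA_integer_, n_snps)
      pmap[snps] <- phase
      confl <- sum((pmap[ei[in_blk]] != pmap[ej[in_blk]]) != etrans[in_blk])
      n_nontree <- length(in_blk) - (k - 1L)
      list(snps = snps, phase01 = phase,
           span_bp = if (!is.null(positions))
             max(positions[snps]) - min(positions[snps]) else NA_real_,
           conflicts = confl, n_nontree = n_nontree,
           low_confidence = n_nontree > 0L && confl > 0.05 * n_nontree)
    })
    names(blocks) <- NULL
    for (b in blocks) r[b$snps] <- b$phase01
  }
  structure(list(blocks = blocks, n_snps = n_snps,
                 min_support = min_support, min_ratio = min_ratio,
                 strand0_allele = r),
            class = "phase_blocks")
}

#' @export
print.phase_blocks <- function(x, ...) {
  ns <- vapply(x$blocks, function(b) length(b$snps), 1L)
  cat(sprintf("<phase_blocks> %d blocks over %d/%d SNPs (largest %d SNPs)\n",
              length(x$blocks), sum(ns), x$n_snps,
              if (length(ns)) max(ns) else 0L))
  invisible(x)
}

# Mutation-supporting / wild-type-supporting barcode sets for any
# mutation class. Point mutations are resolved from reads$mutation_obs;
# SVs are delegated to the structural-variant evidence scan.
mutation_support_sets <- function(reads, mutation, flank_bp = NULL) {
  if (mutation$kind == "point") {
    mo <- reads$mutation_obs
    if (is.null(mo) || nrow(mo) == 0L) {
      stop_hapdose("mutation not linkable: no reads observe the point mutation")
    }
    dt <- data.table::as.data.table(mo)
    agg <- dt[, list(mut_n = sum(allele == 1L), wt_n = sum(allele == 0L)),
              by = "barcode"]
    list(mutant = agg[mut_n > wt_n]$barcode,
         wildtype = agg[wt_n > mut_n]$barcode)
  } else {
    sv_supporting_barcodes(reads, mutation, flank_bp = flank_bp)
  }
}

#' Anchor phase blocks to the mutation: designate HapA and HapB
#'
#' Barcodes that support the mutation (mutation-allele reads for a point
#' mutation; deletion-junction or duplication-divergent gems for an SV)
#' vote on the strand of every block they touch; the strand sharing
#' majority support with the mutation is labelled HapA, its complement
#' HapB. Blocks without direct mutation evidence are chained to anchored
#' blocks through shared barcodes (a maximum-support spanning tree over
#' the block graph rooted at the mutation node); blocks that cannot be
#' reached stay unanchored and are excluded from the HapA/HapB vectors.
#'
#' @param blocks a \code{phase_blocks} object.
#' @param mutation an \code{\link{sv_mutation}}.
#' @param matrix the \code{barcode_matrix} the blocks were built from.
#' @param reads the \code{barcoded_read_set}.
#' @param mutant_barcodes,wildtype_barcodes optional explicit barcode
#'   sets (e.g. from an SV linkage result); derived from \code{reads}
#'   when \code{NULL}.
#' @return a \code{haplotype_pair}: list with \code{hapA}, \code{hapB}
#'   (allele01 vectors over all SNPs, NA where unphased or unanchored),
#'   \code{unphased_snps}, \code{anchor_evidence} (number of
#'   mutation-supporting barcodes), \code{pos}, \code{blocks} and
#'   \code{anchored} (block indices).
#' @export
anchor_hapA <- function(blocks, mutation, matrix, reads,
                        mutant_barcodes = NULL, wildtype_barcodes = NULL) {
  stopifnot(inherits(blocks, "phase_blocks"))
  if (is.null(mutant_barcodes)) {
    sets <- mutation_support_sets(reads, mutation,
                                  flank_bp = 1.5 * reads$params$molecule_mean_len)
    mutant_barcodes <- sets$mutant
    wildtype_barcodes <- wildtype_barcodes %||% sets$wildtype
  }
  if (!length(mutant_barcodes)) {
    stop_hapdose("mutation not linkable: no mutation-supporting barcodes")
  }
  n_snps <- blocks$n_snps
  B <- length(blocks$blocks)
  if (!B) stop_hapdose("anchor_hapA: no phase blocks to anchor")
  blk_of <- rep(NA_integer_, n_snps)
  ph_of <- rep(NA_integer_, n_snps)
  for (k in seq_len(B)) {
    blk_of[blocks$blocks[[k]]$snps] <- k
    ph_of[blocks$blocks[[k]]$snps] <- blocks$blocks[[k]]$phase01
  }
  calls <- barcode_calls(matrix)
  calls <- calls[!is.na(blk_of[snp])]
  calls[, blk := blk_of[snp]]
  calls[, agree := as.integer(call == ph_of[snp])]
  # signed per-(barcode, block) orientation vote
  votes <- calls[, list(v = sum(agree) - sum(1L - agree)), by = c("barcode", "blk")]
  votes <- votes[v != 0L]
  votes[, sgn := sign(v)]
  # mutation pseudo-node = block B + 1
  mnode <- B + 1L
  mv <- data.table::data.table(
    barcode = c(mutant_barcodes, wildtype_barcodes),
    blk = mnode,
    v = c(rep(1L, length(mutant_barcodes)), rep(-1L, length(wildtype_barcodes))),
    sgn = c(rep(1L, length(mutant_barcodes)), rep(-1L, length(wildtype_barcodes))))
  nodes <- rbind(votes, mv)
  # block-level edges: every node pair sharing a barcode votes by sign
  grp <- split(seq_len(nrow(nodes)), nodes$barcode)
  nb <- nodes$blk; ns <- nodes$sgn
  pieces <- lapply(grp, function(ix) {
    k <- length(ix)
    if (k < 2L) return(NULL)
    ixo <- ix[order(nb[ix])]
    i1 <- rep.int(seq_len(k - 1L), (k - 1L):1L)
    i2 <- sequence((k - 1L):1L, from = 2:k)
    list(nb[ixo][i1], nb[ixo][i2], ns[ixo][i1] == ns[ixo][i2])
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  hapA <- rep(NA_integer_, n_snps)
  anchored <- integer()
  if (length(pieces)) {
    be <- data.table::data.table(
      i = unlist(lapply(pieces, `[[`, 1L), use.names = FALSE),
      j = unlist(lapply(pieces, `[[`, 2L), use.names = FALSE),
      same = unlist(lapply(pieces, `[[`, 3L), use.names = FALSE))
    be <- be[i != j] # a barcode may span a block twice only via itself
    eg <- be[, list(cis = sum(same), trans = sum(!same)), by = c("i", "j")]
    eg <- eg[cis != trans] # ambiguous block links are unusable
    if (nrow(eg)) {
      etrans <- eg$trans > eg$cis
      kr <- .kruskal(eg$i, eg$j, pmax(eg$cis, eg$trans), mnode)
      o <- .orient_forest(eg$i[kr$tree], eg$j[kr$tree], etrans[kr$tree],
                          mnode, roots = mnode)
      # o == 0 for nodes in the mutation component, oriented like M
      for (k in seq_len(B)) {
        if (is.na(o[k])) next
        anchored <- c(anchored, k)
        snps <- blocks$blocks[[k]]$snps
        ph <- blocks$blocks[[k]]$phase01
        hapA[snps] <- if (o[k] == 0L) ph else 1L - ph
      }
    }
  }
  if (!length(anchored)) {
    stop_hapdose("mutation not linkable: no block reachable from mutation-supporting barcodes")
  }
  structure(list(hapA = hapA, hapB = ifelse(is.na(hapA), NA_integer_, 1L - hapA),
                 unphased_snps = which(is.na(hapA)),
                 anchor_evidence = length(mutant_barcodes),
                 pos = reads$snp_pos, blocks = blocks, anchored = anchored,
                 mutation = mutation),
            class = "haplotype_pair")
}

#' @export
print.haplotype_pair <- function(x, ...) {
  cat(sprintf(paste0("<haplotype_pair> %d/%d SNPs phased and anchored ",
                     "(%d blocks anchored, %d mutation-supporting barcodes)\n"),
              sum(!is.na(x$hapA)), length(x$hapA), length(x$anchored),
              x$anchor_evidence))
  invisible(x)
}

#' Phase and anchor in one call
#'
#' Convenience wrapper: barcode matrix, phase graph, block calling and
#' HapA/HapB anchoring.
#'
#' @inheritParams call_phase_blocks
#' @inheritParams anchor_hapA
#' @param reads a \code{barcoded_read_set}.
#' @param mutation an \code{\link{sv_mutation}}.
#' @return a \code{haplotype_pair}.
#' @export
phase_linked_reads <- function(reads, mutation, min_support = 2L,
                               min_ratio = 0.75, mutant_barcodes = NULL,
                               wildtype_barcodes = NULL) {
  m <- build_barcode_matrix(reads)
  g <- build_phase_graph(m)
  b <- call_phase_blocks(g, min_support = min_support, min_ratio = min_ratio,
                         positions = reads$snp_pos)
  anchor_hapA(b, mutation, m, reads, mutant_barcodes = mutant_barcodes,
              wildtype_barcodes = wildtype_barcodes)
}

#' N50 phase-block length
#'
#' The standard contiguity summary: the largest length L such that
#' blocks of span >= L together cover at least half the total phased
#' span.
#'
#' @param blocks a \code{phase_blocks} object, or a numeric vector of
#'   block spans in bp.
#' @return N50 span in bp.
#' @export
n50_phase_block <- function(blocks) {
  spans <- if (inherits(blocks, "phase_blocks")) {
    vapply(blocks$blocks, function(b) b$span_bp, 1)
  } else as.numeric(blocks)
  if (!length(spans) || anyNA(spans)) {
    stop_hapdose("n50_phase_block: no blocks with defined spans")
  }
  spans <- sort(spans, decreasing = TRUE)
  spans[which(cumsum(spans) >= sum(spans) / 2)[1L]]
}

#' Concordance of an anchored haplotype with truth
#'
#' Fraction of phased SNPs at which the HapA vector matches a truth
#' allele vector, plus the switch-error count (flips of the
#' match/mismatch state between consecutive phased SNPs).
#'
#' @param pair a \code{haplotype_pair}.
#' @param truth01 integer 0/1 allele vector over all SNPs (e.g.
#'   \code{\link{truth_hapA}} of the simulated diplotype).
#' @return list with \code{concordance}, \code{switch_errors},
#'   \code{n_phased}.
#' @export
phasing_concordance <- function(pair, truth01) {
  stopifnot(inherits(pair, "haplotype_pair"))
  if (length(truth01) != length(pair$hapA)) {
    stop_hapdose("phasing_concordance: truth length %d != %d SNPs",
                 length(truth01), length(pair$hapA))
  }
  idx <- which(!is.na(pair$hapA) & !is.na(truth01))
  if (!length(idx)) stop_hapdose("phasing_concordance: no phased SNP overlaps truth")
  m <- pair$hapA[idx] == truth01[idx]
  list(concordance = mean(m),
       switch_errors = if (length(m) > 1L) sum(m[-1L] != m[-length(m)]) else 0L,
       n_phased = length(idx))
}
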