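# Independent oracles used across the suite.  These deliberately avoid the
# package's own quartet / Fitch code paths: quartet topologies come from
# ape::prop.part clusters, Fitch lengths from exhaustive internal-labeling
# enumeration or phangorn, optimal trees from scoring phangorn::allTrees.

# quartet status counts by brute force over ape::prop.part clusters
oracle_quartet_counts <- function(t1, t2) {
  labs <- sort(t1$tip.label)
  n <- length(labs)
  topo_of <- function(phy) {
    pp <- ape::prop.part(phy)
    clus <- lapply(pp, function(ix) attr(pp, "labels")[ix])
    q <- utils::combn(labs, 4L)
    topo <- integer(ncol(q))
    for (i in seq_len(ncol(q))) {
      quad <- q[, i]
      for (cl in clus) {
        inside <- quad %in% cl
        if (sum(inside) == 2) {
          pair <- sort(which(inside))
          code <- if (all(pair == c(1, 2)) || all(pair == c(3, 4))) {
            1L
          } else if (all(pair == c(1, 3)) || all(pair == c(2, 4))) {
            2L
          } else {
            3L
          }
          topo[i] <- code
          break
        }
      }
    }
    topo
  }
  topo1 <- topo_of(t1)
  topo2 <- topo_of(t2)
  r1 <- topo1 > 0L
  r2 <- topo2 > 0L
  list(
    Q = length(topo1),
    s = sum(r1 & r2 & topo1 == topo2),
    d = sum(r1 & r2 & topo1 != topo2),
    r1 = sum(r1 & !r2),
    r2 = sum(!r1 & r2),
    u = sum(!r1 & !r2)
  )
}

# exhaustive Fitch length: minimum over all internal-node labelings
# (leaf states must be single symbols)
oracle_fitch_exhaustive <- function(phy, leaf_states, alphabet) {
  n <- length(phy$tip.label)
  edge <- phy$edge
  internal <- sort(unique(edge[, 1]))
  grid <- do.call(
    expand.grid,
    c(rep(list(alphabet), length(internal)), stringsAsFactors = FALSE)
  )
  best <- Inf
  leaf_vec <- leaf_states[phy$tip.label]
  for (r in seq_len(nrow(grid))) {
    assign_ <- character(n + length(internal))
    assign_[seq_len(n)] <- leaf_vec
    assign_[internal] <- as.character(unlist(grid[r, ]))
    changes <- sum(assign_[edge[, 1]] != assign_[edge[, 2]])
    if (changes < best) best <- changes
  }
  best
}

# random character matrix over a fixed taxon set
random_char_matrix <- function(taxa, nchar, n_states = 2,
                               missing_frac = 0, seed = NULL) {
  draw <- function() {
    dat <- matrix(
      sample(as.character(seq_len(n_states) - 1L), length(taxa) * nchar,
        replace = TRUE
      ),
      length(taxa), nchar,
      dimnames = list(taxa, NULL)
    )
    if (missing_frac > 0) {
      dat[matrix(stats::runif(length(dat)) < missing_frac, nrow(dat))] <- "?"
    }
    dat
  }
  dat <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  char_matrix(dat)
}

# random unrooted binary tree over given labels
random_tree <- function(labels, seed = NULL) {
  gen <- function() ape::rtree(length(labels), tip.label = sample(labels))
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# phyDat conversion for phangorn cross-checks (single-symbol cells only)
as_phyDat <- function(m) {
  lv <- sort(unique(as.vector(m$data[m$data != "?" & m$data != "-"])))
  dat <- m$data
  dat[dat == "-"] <- "?"
  phangorn::phyDat(dat, type = "USER", levels = lv, ambiguity = "?")
}
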