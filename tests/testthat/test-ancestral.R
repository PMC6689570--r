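rooted_tree <- function(text, outgroup) {
  phy <- parse_tree(text)
  ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
}

test_that("unique reconstructions are identical under acctran and deltran", {
  phy <- rooted_tree("((A,B),(C,D));", "A")
  m <- char_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
  anc <- reconstruct_ancestral_states(phy, m)
  st <- anc$states
  expect_equal(st$acctran, st$deltran)
  expect_equal(anc$steps, 1L)

  const <- char_matrix(rbind(A = "2", B = "2", C = "2", D = "2"))
  anc_c <- reconstruct_ancestral_states(phy, const)
  expect_true(all(anc_c$states$acctran == "2"))
  expect_true(all(anc_c$states$deltran == "2"))
  expect_equal(anc_c$steps, 0L)

  expect_error(
    reconstruct_ancestral_states(ape::unroot(parse_tree("((A,B),(C,D),E);")), m),
    "rooted"
  )
})

test_that("both modes imply exactly the Fitch length on random binary trees", {
  for (seed in 1:6) {
    n <- withr::with_seed(seed, sample(5:6, 1))
    labs <- paste0("t", seq_len(n))
    phy <- ape::root(random_tree(labs, seed = seed),
      outgroup = labs[1], resolve.root = TRUE
    )
    m <- random_char_matrix(labs, nchar = 15, n_states = 2, seed = seed + 40)
    anc <- reconstruct_ancestral_states(phy, m)
    fl <- fitch_length(phy, m)$steps
    expect_equal(anc$steps, fl)
    expect_equal(implied_changes(phy, m, anc, "acctran"), fl)
    expect_equal(implied_changes(phy, m, anc, "deltran"), fl)
    # resolved states always belong to the MPR set
    st <- anc$states
    ok_acc <- mapply(grepl, st$acctran, st$mpr, MoreArgs = list(fixed = TRUE))
    ok_del <- mapply(grepl, st$deltran, st$mpr, MoreArgs = list(fixed = TRUE))
    expect_true(all(ok_acc) && all(ok_del))
  }
})

test_that("acctran pulls changes rootward and deltran delays them", {
  # 0 at the outgroup side, 1 at two distant tips: the classic case where
  # acctran infers an early gain + loss and deltran two late gains
  phy <- rooted_tree("(A,(B,((C,D),(E,F))));", "A")
  m <- char_matrix(rbind(A = "0", B = "0", C = "1", D = "1", E = "0", F = "0"))
  anc <- reconstruct_ancestral_states(phy, m)
  st <- anc$states
  expect_equal(anc$steps, 1L)
  expect_equal(st$acctran, st$deltran) # unique MPR here

  m2 <- char_matrix(rbind(A = "0", B = "0", C = "1", D = "1", E = "1", F = "1"))
  anc2 <- reconstruct_ancestral_states(phy, m2)
  expect_equal(anc2$steps, 1L)
  st2 <- anc2$states
  # the ancestor of {C,D,E,F} is 1 under both modes (unique MPR)
  cdef <- ape::getMRCA(phy, c("C", "D", "E", "F"))
  expect_equal(st2$acctran[st2$node == cdef], "1")
  expect_equal(st2$deltran[st2$node == cdef], "1")
})

test_that("export_hypothetical_ancestors yields one row per internal node that adds no steps", {
  labs <- sprintf("t%02d", 1:12)
  for (seed in 1:3) {
    ref <- ape::root(random_tree(labs, seed = seed),
      outgroup = labs[1], resolve.root = TRUE
    )
    m <- random_char_matrix(labs,
      nchar = 30, n_states = 3,
      missing_frac = 0.1, seed = seed + 60
    )
    for (mode in c("acctran", "deltran")) {
      ha <- export_hypothetical_ancestors(ref, m, mode = mode)
      expect_equal(nrow(ha$data), ref$Nnode)
      # graft each ancestor as a zero-length child of its node: total
      # parsimony length must not change
      total0 <- fitch_length(ref, m, exact = TRUE)$total
      desc <- lapply(seq_len(nrow(ha$data)), function(i) {
        node <- as.integer(sub("hta_", "", ha$taxa[i]))
        tips <- phangorn::Descendants(ref, node, "tips")[[1]]
        ref$tip.label[tips]
      })
      grown <- ref
      grown$edge.length <- rep(1, nrow(grown$edge))
      for (i in seq_len(nrow(ha$data))) {
        where <- if (length(desc[[i]]) == length(labs)) {
          length(grown$tip.label) + 1L # root
        } else {
          ape::getMRCA(grown, desc[[i]])
        }
        grown <- phytools::bind.tip(grown, ha$taxa[i],
          edge.length = 0, where = where
        )
      }
      expect_setequal(grown$tip.label, c(labs, ha$taxa))
      comb <- bind_taxa(m, ha)
      expect_equal(fitch_length(grown, comb, exact = TRUE)$total, total0)
    }
  }
})

test_that("ancestor export preserves inapplicability and constant states", {
  ref <- rooted_tree("((A,B),(C,D));", "A")
  m1 <- char_matrix(rbind(A = "1", B = "1", C = "1", D = "1"))
  ha <- export_hypothetical_ancestors(ref, m1)
  expect_true(all(ha$data == "1"))

  # characters inapplicable in an entire subtree stay inapplicable there
  m2 <- char_matrix(rbind(A = "0", B = "0", C = "-", D = "-"))
  ha2 <- export_hypothetical_ancestors(ref, m2)
  cd_node <- ape::getMRCA(ref, c("C", "D"))
  expect_equal(unname(ha2$data[paste0("hta_", cd_node), 1]), "-")
  ab_node <- ape::getMRCA(ref, c("A", "B"))
  expect_equal(unname(ha2$data[paste0("hta_", ab_node), 1]), "0")
})

test_that("acctran and deltran rows differ only where the MPR set is ambiguous", {
  labs <- paste0("t", 1:8)
  for (seed in 4:6) {
    ref <- ape::root(random_tree(labs, seed = seed),
      outgroup = labs[1], resolve.root = TRUE
    )
    m <- random_char_matrix(labs, nchar = 40, n_states = 2, seed = seed + 80)
    acc <- export_hypothetical_ancestors(ref, m, mode = "acctran")
    del <- export_hypothetical_ancestors(ref, m, mode = "deltran")
    anc <- reconstruct_ancestral_states(ref, m)
    differs <- acc$data != del$data
    if (any(differs)) {
      idx <- which(differs, arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        node <- as.integer(sub("hta_", "", rownames(differs)[idx[r, 1]]))
        ch <- colnames(differs)[idx[r, 2]]
        mpr <- anc$states$mpr[anc$states$node == node & anc$states$character == ch]
        expect_gt(nchar(mpr), 1)
      }
    }
    succeed()
  }
})

test_that("reconstruction handles polytomies in the reference topology", {
  ref <- rooted_tree("((A,B,C),(D,E),F);", "F")
  m <- char_matrix(rbind(A = "0", B = "0", C = "1", D = "1", E = "1", F = "0"))
  anc <- reconstruct_ancestral_states(ref, m)
  expect_equal(anc$steps, fitch_length(ref, m, exact = TRUE)$steps)
  ha <- export_hypothetical_ancestors(ref, m)
  expect_equal(nrow(ha$data), ref$Nnode)
})
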