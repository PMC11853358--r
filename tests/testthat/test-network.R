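# Residue interaction networks, communities, betweenness.

test_that("edge weights follow -log|C| with a recorded floor", {
  g <- residue_graph(
    data.frame(id = c("A:1", "A:2", "A:3"), chain = "A", resno = 1:3),
    data.frame(from = c("A:1", "A:2", "A:1"), to = c("A:2", "A:3", "A:3"),
               absC = c(1, 0.5, 1e-9), persistence = 1))
  expect_equal(g$edges$weight[1], 0)
  expect_equal(g$edges$weight[2], log(2), tolerance = 1e-6)
  expect_equal(g$edges$weight[3], -log(1e-6))   # floored
  expect_error(residue_graph(g$nodes,
    data.frame(from = "A:1", to = "A:1", absC = 1, persistence = 1)),
    "self-edges")
})

test_that("network edges require persistence at or above the threshold", {
  # two contact schedules: 0.75 makes an edge, 0.74 does not
  spec <- synthetic_spec(
    chains = list(
      M = data.frame(resno = 1:3, resname = "GLY", block = "A"),
      P = data.frame(resno = 11:13, resname = "GLY", block = "B")),
    block_centers = list(A = c(0, 6.5, 0), B = c(0, -6.5, 0)),
    schedules = data.frame(resA = c("M:1", "M:2"), resB = c("P:11", "P:12"),
                           type = "contact", occupancy = c(0.75, 0.74)),
    noise_sd = 0.05, frames = 100L, seed = 9)
  sim <- simulate_trajectory(make_complex(spec), spec)
  d <- dccm(sim$trajectory, "ca", fit = FALSE)
  net <- build_network(sim$trajectory, d, persistence = 0.75)
  key <- paste(net$edges$from, net$edges$to)
  expect_true("M:1 P:11" %in% key)
  expect_false("M:2 P:12" %in% key)
  expect_false(any(grepl("^M:2 P|P:12", key[grepl("M:2", key)])))
})

test_that("Girvan-Newman splits two bridged cliques like the exhaustive oracle", {
  e <- two_clique_edges()
  g <- graph_from_edges(8, e)
  part <- girvan_newman(g, min_size = 3)
  oracle <- best_partition_bruteforce(8, e)
  mem <- part$membership[paste0("A:", 1:8)]
  # same partition up to label permutation
  expect_equal(length(unique(mem)), length(unique(oracle$membership)))
  expect_true(all(table(mem, oracle$membership) %in%
                    c(0, table(oracle$membership))))
  expect_equal(part$modularity, oracle$modularity, tolerance = 1e-9)
  expect_equal(sort(vapply(part$communities, length, 1L)), c(4L, 4L))
})

test_that("a complete graph is one community; tiny ones are filtered", {
  e5 <- as.data.frame(t(utils::combn(1:5, 2)))
  names(e5) <- c("i", "j")
  g5 <- graph_from_edges(5, e5)
  p5 <- girvan_newman(g5)
  expect_equal(length(unique(p5$membership)), 1L)
  # two 4-cliques plus an isolated connected pair, min_size 3
  e <- rbind(two_clique_edges(), data.frame(i = 9, j = 10))
  g <- graph_from_edges(10, e)
  p <- girvan_newman(g, min_size = 3)
  expect_equal(length(p$communities), 2L)          # the pair is omitted
  expect_equal(length(unique(p$membership)), 3L)   # but still recorded
  expect_false(any(vapply(p$communities, function(cc) "A:9" %in% cc, TRUE)))
})

test_that("betweenness matches hand-checkable graphs", {
  # path a-b-c: the middle node carries the single dependency
  gp <- graph_from_edges(3, data.frame(i = c(1, 2), j = c(2, 3)))
  bp <- graph_betweenness(gp)
  expect_equal(unname(bp$node[c("A:1", "A:2", "A:3")]), c(0, 1, 0))
  # star: center maximal, leaves zero
  gs <- graph_from_edges(5, data.frame(i = 1, j = 2:5))
  bs <- graph_betweenness(gs)
  expect_equal(unname(bs$node["A:1"]), choose(4, 2))
  expect_equal(unname(bs$node[paste0("A:", 2:5)]), rep(0, 4))
  # complete graph: all edge betweenness equal by symmetry
  e5 <- as.data.frame(t(utils::combn(1:5, 2)))
  names(e5) <- c("i", "j")
  be <- graph_betweenness(graph_from_edges(5, e5))$edge$betweenness
  expect_equal(be, rep(be[1], length(be)))
})

test_that("weighted betweenness equals exhaustive path enumeration", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(4:7, 1)
    e <- random_connected_graph(n)
    nodes <- data.frame(id = paste0("A:", 1:n), chain = "A", resno = 1:n)
    edges <- data.frame(from = paste0("A:", e$i), to = paste0("A:", e$j),
                        absC = exp(-e$w), persistence = 1)
    g <- residue_graph(nodes, edges)
    got <- graph_betweenness(g)
    want <- brute_betweenness(n, e)
    expect_equal(unname(got$node[paste0("A:", 1:n)]), want$node,
                 tolerance = 1e-9)
    key_got <- paste(got$edge$from, got$edge$to)
    key_want <- paste(paste0("A:", pmin(e$i, e$j)),
                      paste0("A:", pmax(e$i, e$j)))
    expect_equal(got$edge$betweenness[match(key_want, key_got)], want$edge,
                 tolerance = 1e-9)
  }
})

test_that("intercommunity strength sums |C| over crossing edges", {
  e <- two_clique_edges()
  g <- graph_from_edges(8, e, absC = 0.8)
  part <- girvan_newman(g, min_size = 3)
  cs <- intercommunity_strength(g, part)
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$strength, 0.8)      # the single bridge edge
  expect_equal(cs$n_edges, 1L)
  # mass conservation: crossing + within = total edge |C| mass
  within <- sum(g$edges$absC) - sum(cs$strength)
  mem <- part$membership
  same <- mem[g$edges$from] == mem[g$edges$to]
  expect_equal(within, sum(g$edges$absC[same]), tolerance = 1e-12)
  # no crossing edges at all
  mem_all <- stats::setNames(rep(1L, 8), paste0("A:", 1:8))
  p1 <- structure(list(membership = mem_all,
                       communities = list(paste0("A:", 1:8)),
                       modularity = 0, min_size = 3),
                  class = "community_partition")
  expect_equal(nrow(intercommunity_strength(g, p1)), 0L)
})

test_that("planted two-block networks are recovered for every seed", {
  for (seed in 1:20) {
    spec <- two_block_spec(seed)
    sim <- simulate_trajectory(make_complex(spec), spec)
    d <- dccm(sim$trajectory, "ca", fit = FALSE)
    net <- build_network(sim$trajectory, d)
    part <- girvan_newman(net)
    mem <- part$membership
    truth <- sim$truth$blocks[names(mem)]
    expect_equal(length(unique(mem)), 2L, label = paste("seed", seed))
    expect_true(all(table(mem, truth) %in% c(0L, 6L)),
                label = paste("seed", seed, "partition"))
  }
})

test_that("graph writers emit the documented formats", {
  g <- graph_from_edges(8, two_clique_edges())
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_network_edges(g, p1)
  tab <- utils::read.table(p1, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), nrow(g$edges))
  expect_named(tab, c("resA", "resB", "weight", "absC", "persistence"))
  part <- girvan_newman(g)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_communities(g, part, p2)
  ct <- utils::read.table(p2, header = TRUE, sep = "\t")
  expect_named(ct, c("resnum", "chain", "community"))
  p3 <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(g, p3)
  expect_true(file.size(p3) > 0)
})
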