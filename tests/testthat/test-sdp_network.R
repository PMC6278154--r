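test_that("the degree rule classifies SDP, pSDP and unsupported", {
  cov <- fake_cov(data.frame(col_i = c(1, 1), col_j = c(2, 3), z = c(7, 8)))
  net <- build_network(c(1, 2, 3), cov, z_threshold = 6.5)
  cls <- setNames(net$nodes$class, net$nodes$column)
  expect_equal(unname(cls[c("1", "2", "3")]), c("SDP", "pSDP", "pSDP"))
  expect_equal(length(net$components), 1)
  expect_setequal(net$components[[1]], c(1, 2, 3))

  # a single connected pair: both pSDP
  cov2 <- fake_cov(data.frame(col_i = 1, col_j = 2, z = 7))
  net2 <- build_network(c(1, 2), cov2)
  expect_equal(net2$nodes$class, c("pSDP", "pSDP"))

  # no edge reaches the threshold: all unsupported, zero SDNs
  cov3 <- fake_cov(data.frame(col_i = 1, col_j = 2, z = 2))
  net3 <- build_network(c(1, 2), cov3)
  expect_true(all(net3$nodes$class == "unsupported"))
  expect_equal(length(net3$components), 0)
})

test_that("a CDP absent from the covariation result is a coverage error", {
  cov <- fake_cov(data.frame(col_i = 1, col_j = 2, z = 7))
  expect_error(build_network(c(1, 2, 9), cov), "not covered.*9")
})

test_that("lowering the threshold only adds edges and promotes classes", {
  set.seed(13)
  n <- 20
  pairs <- t(combn(n, 2))
  cov <- fake_cov(data.frame(col_i = pairs[, 1], col_j = pairs[, 2],
                             z = rnorm(nrow(pairs), 3, 3)))
  rank_of <- c(unsupported = 0, pSDP = 1, SDP = 2)
  prev <- NULL
  for (thr in c(8, 6.5, 4, 1, -2)) {
    net <- build_network(1:n, cov, z_threshold = thr)
    if (!is.null(prev)) {
      key <- function(e) paste(e$col_i, e$col_j)
      expect_true(all(key(prev$edges) %in% key(net$edges)))
      expect_true(all(rank_of[net$nodes$class] >= rank_of[prev$nodes$class]))
    }
    prev <- net
  }
})

test_that("SDN extraction agrees with a union-find oracle on random graphs", {
  set.seed(29)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    pairs <- t(combn(n, 2))
    z <- ifelse(runif(nrow(pairs)) < 0.06, 8, 0)
    cov <- fake_cov(data.frame(col_i = pairs[, 1], col_j = pairs[, 2], z = z))
    net <- build_network(1:n, cov)
    edges <- cov$pairs[cov$pairs$z >= 6.5, c("col_i", "col_j")]
    oracle <- uf_components(1:n, edges)
    got <- lapply(net$components, sort)
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(oracle, paste, collapse = ","))
    # degrees against direct counting
    for (v in 1:n) {
      expect_equal(net$nodes$degree[net$nodes$column == v],
                   sum(edges == v))
    }
  }
})

test_that("key SDPs intersect the SDP sets of two reference-mapped networks", {
  # star networks: centre connected to every other node -> centre and any
  # node with >= 2 links are SDP
  mk_net <- function(cols, edges) {
    build_network(cols, fake_cov(edges, cols))
  }
  # network A: SDPs at columns 10,20,30 (triangle), pSDP at 40
  net_a <- mk_net(c(10, 20, 30, 40),
                  data.frame(col_i = c(10, 10, 20, 30),
                             col_j = c(20, 30, 30, 40), z = c(7, 7, 7, 7)))
  # network B over different columns mapped to overlapping references
  net_b <- mk_net(c(1, 2, 3),
                  data.frame(col_i = c(1, 1, 2), col_j = c(2, 3, 3),
                             z = c(7, 7, 7)))
  # reference numbering: A cols 10,20,30,40 -> 89,307,343,346
  aln_a <- mk_aln(paste(c(rep("-", 9), "A", rep("-", 9), "C", rep("-", 9),
                          "D", rep("-", 9), "E"), collapse = ""), "ref")
  map_a <- build_column_map(aln_a, "ref", 89)
  map_a$col_to_ref[] <- c(89L, 307L, 343L, 346L)
  map_a$ref_to_col <- setNames(as.integer(names(map_a$col_to_ref)),
                               map_a$col_to_ref)
  # B cols 1,2,3 -> 307,343,999
  aln_b <- mk_aln("ACD", "ref")
  map_b <- build_column_map(aln_b, "ref", 1)
  map_b$col_to_ref[] <- c(307L, 343L, 999L)
  map_b$ref_to_col <- setNames(as.integer(names(map_b$col_to_ref)),
                               map_b$col_to_ref)

  ks <- key_sdps(net_a, net_b, map_a, map_b)
  expect_equal(as.integer(ks), c(307, 343)) # SDP in both
  # symmetry and idempotence
  ks_rev <- key_sdps(net_b, net_a, map_b, map_a)
  expect_equal(as.integer(ks), as.integer(ks_rev))
  expect_equal(as.integer(key_sdps(net_a, net_a, map_a, map_a)),
               sort(unname(map_a$col_to_ref[as.character(
                 network_columns(net_a, "SDP"))])))
  # disjoint SDP sets -> empty
  net_c <- mk_net(c(1, 2, 3),
                  data.frame(col_i = c(1, 1, 2), col_j = c(2, 3, 3), z = 7))
  map_c <- map_b
  map_c$col_to_ref[] <- c(7001L, 7002L, 7003L)
  expect_length(key_sdps(net_a, net_c, map_a, map_c), 0)
})

test_that("unmapped SDP columns are reported, never dropped", {
  net <- build_network(c(1, 2, 3),
                       fake_cov(data.frame(col_i = c(1, 1, 2),
                                           col_j = c(2, 3, 3), z = 7)))
  aln <- mk_aln("A-C", "ref") # column 2 unmapped
  cm <- build_column_map(aln, "ref", 10)
  ks <- key_sdps(net, net, cm, cm)
  expect_true(2 %in% attr(ks, "unmapped")$a)
  expect_false(2 %in% ks)
})

test_that("the connectivity table reports class, degree and SDN per network", {
  # chain a-b-c: degrees 1,2,1
  net <- build_network(c(1, 2, 3),
                       fake_cov(data.frame(col_i = c(1, 2), col_j = c(2, 3),
                                           z = 7)))
  cm <- build_column_map(mk_aln("ACD", "ref"), "ref", 1)
  tab <- connectivity_table(list(net), list(cm), names = "x")
  expect_equal(tab$degree_x, c(1, 2, 1))
  expect_equal(tab$class_x, c("pSDP", "SDP", "pSDP"))
  expect_equal(tab$sdn_x, c(1, 1, 1))

  # a position present in one network only shows NA in the other
  net2 <- build_network(c(1, 2),
                        fake_cov(data.frame(col_i = 1, col_j = 2, z = 7)))
  tab2 <- connectivity_table(list(net, net2), list(cm, cm),
                             names = c("x", "y"))
  expect_true(is.na(tab2$class_y[tab2$ref_position == 3]))
})

test_that("threshold sweeps are monotone and expose SDN merge points", {
  # two triangles bridged by one weak edge (z = 3)
  edges <- data.frame(col_i = c(1, 1, 2, 4, 4, 5, 3),
                      col_j = c(2, 3, 3, 5, 6, 6, 4),
                      z = c(8, 8, 8, 8, 8, 8, 3))
  cov <- fake_cov(edges)
  sweep <- threshold_sweep(1:6, cov, c(9, 6.5, 2))
  expect_equal(sweep$n_edges, c(0, 6, 7)) # non-decreasing as z drops
  expect_equal(sweep$n_sdn, c(0, 2, 1))   # the two SDNs merge below z = 3
  expect_error(threshold_sweep(1:6, cov, numeric(0)), "non-empty")
})

test_that("network export writes edge list, GraphML and summary", {
  net <- build_network(c(1, 2, 3),
                       fake_cov(data.frame(col_i = c(1, 1), col_j = c(2, 3),
                                           z = 7)))
  ep <- withr::local_tempfile(fileext = ".tsv")
  gp <- withr::local_tempfile(fileext = ".graphml")
  sp <- withr::local_tempfile(fileext = ".json")
  write_network(net, ep, gp)
  write_network_summary(net, sp)
  expect_equal(nrow(read.delim(ep)), 2)
  expect_true(any(grepl("graphml", readLines(gp))))
  expect_equal(jsonlite::read_json(sp)$n_edges, 2)
})
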