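# CSV dialect parsing, validation and round trips.

write_lines <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

test_that("a minimal 2x2 matrix parses with row = parent, column = child", {
  path <- write_lines(c(",A,B", "A,,4", "B,,"))
  net <- read_network(path)
  expect_equal(net$nodes, c("A", "B"))
  expect_equal(net$edges,
               data.frame(parent = "A", child = "B", strength = 4L))
})

test_that("decimal cells fail cleanly, naming the offending cell", {
  path <- write_lines(c(",A,B", "A,,2.5", "B,,"))
  expect_error(read_network(path), "A -> B.*2\\.5")
})

test_that("matrix validation rejects malformed inputs", {
  expect_error(read_network(write_lines(c(",A,A", "A,,", "A,,"))),
               "duplicate")
  expect_error(read_network(write_lines(c(",A,B", "A,,4", "C,,"))),
               "disagree")
  expect_error(read_network(write_lines(c(",A,B", "A,2,", "B,,"))),
               "self-edge")
  expect_error(read_network(write_lines(c(",A,B", "A,,7", "B,,"))),
               "range")
  expect_warning(net <- read_network(write_lines(c(",A,B", "A,0,4", "B,,"))),
                 "no edge")
  expect_equal(nrow(net$edges), 1L)
})

test_that("edge count of a generated matrix matches an independent CSV scan", {
  spec <- generator_spec(n_nodes = 7, density = 0.25, seed = 11)
  path <- tempfile(fileext = ".csv")
  write_network(random_network(spec), path)
  net <- read_network(path)
  # independent scan: count non-blank body cells of the raw file
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = "character")
  filled <- sum(trimws(as.matrix(raw[, -1])) != "")
  expect_equal(nrow(net$edges), filled)
  expect_equal(length(net$nodes), 7L)
  expect_equal(net$nodes, names(raw)[-1])  # header order preserved
})

test_that("network round-trips through write_network unchanged", {
  for (seed in c(3, 17)) {
    net <- random_network(generator_spec(n_nodes = 6, density = 0.4,
                                         seed = seed))
    path <- tempfile(fileext = ".csv")
    write_network(net, path)
    back <- read_network(path)
    expect_equal(back$nodes, net$nodes)
    o1 <- net$edges[order(net$edges$parent, net$edges$child), ]
    o2 <- back$edges[order(back$edges$parent, back$edges$child), ]
    rownames(o1) <- rownames(o2) <- NULL
    expect_equal(o2, o1)
  }
})

test_that("node names containing spaces survive a round trip", {
  net <- bbn_network(c("Green Algae", "Limpet"),
                     data.frame(parent = "Limpet", child = "Green Algae",
                                strength = -3L))
  path <- tempfile(fileext = ".csv")
  write_network(net, path)
  expect_equal(read_network(path)$edges$child, "Green Algae")
})

test_that("scenario files read sparse priors, dropping zeros", {
  net <- bbn_network(c("Dogwhelk", "Limpet", "Barnacle"),
                     data.frame(parent = "Dogwhelk", child = "Limpet",
                                strength = -4L))
  path <- write_lines(c("node,value", "Dogwhelk,-4", "Limpet,0",
                        "Barnacle,0"))
  sc <- read_scenario(path, net)
  expect_equal(sc$priors, c(Dogwhelk = -4L))
  # all-zero file -> empty scenario
  path0 <- write_lines(c("node,value", "Dogwhelk,0", "Limpet,0",
                         "Barnacle,0"))
  expect_length(read_scenario(path0, net)$priors, 0L)
})

test_that("scenario validation suggests the nearest label and warns on omissions", {
  net <- bbn_network(c("Dogwhelk", "Limpet"),
                     data.frame(parent = "Dogwhelk", child = "Limpet",
                                strength = -4L))
  bad <- write_lines(c("node,value", "Dogwelk,-4", "Limpet,0"))
  expect_error(read_scenario(bad, net), "Dogwhelk")
  partial <- write_lines(c("node,value", "Dogwhelk,-4"))
  expect_warning(sc <- read_scenario(partial, net), "Limpet")
  expect_equal(sc$priors, c(Dogwhelk = -4L))
  outofrange <- write_lines(c("node,value", "Dogwhelk,9", "Limpet,0"))
  expect_error(read_scenario(outofrange, net), "-4\\.\\.4")
})

test_that("diagram files parse ids and colour classes", {
  path <- write_lines(c("id,node.type,node.name,A,B,C",
                        "s01,1,A,,4,",
                        "s02,2,B,,,-2",
                        "s03,2,C,,,"))
  dn <- read_diagram_network(path)
  expect_s3_class(dn, "bbn_diagram_network")
  expect_equal(dn$id, c("s01", "s02", "s03"))
  expect_equal(dn$node_type, c(1L, 2L, 2L))
  expect_equal(length(unique(dn$node_type)), 2L)
})

test_that("diagram validation rejects bad ids and node types", {
  expect_error(read_diagram_network(
    write_lines(c("id,node.type,node.name,A,B",
                  "s01,5,A,,4", "s02,1,B,,"))), "1\\.\\.4")
  expect_error(read_diagram_network(
    write_lines(c("id,node.type,node.name,A,B",
                  "x1,1,A,,4", "s02,1,B,,"))), "2 digits")
  expect_error(read_diagram_network(
    write_lines(c("wrong,node.type,node.name,A,B",
                  "s01,1,A,,4", "s02,1,B,,"))), "must start")
})

test_that("the two matrix parsers agree on the edge set", {
  net <- random_network(generator_spec(n_nodes = 5, density = 0.5, seed = 7))
  dn_obj <- bbn_diagram_network(net, id = sprintf("s%02d", 1:5),
                                node_type = rep(1:4, length.out = 5))
  plain <- tempfile(fileext = ".csv")
  fancy <- tempfile(fileext = ".csv")
  write_network(net, plain)
  beliefnet:::write_diagram_network(dn_obj, fancy)
  a <- read_network(plain)$edges
  b <- read_diagram_network(fancy)$edges
  a <- a[order(a$parent, a$child), ]
  b <- b[order(b$parent, b$child), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(b, a)
})

test_that("prediction output writes one row per node and round-trips to 6 decimals", {
  toys <- toy_fixtures()
  res <- bbn_predict(toys$web8$network,
                     list(toys$web8$scenario,
                          bbn_scenario(c(Policy = 4), name = "policy_on",
                                       network = toys$web8$network)))
  path <- tempfile(fileext = ".csv")
  df <- write_predictions(res, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(nrow(back), 8L)
  expect_equal(names(back), c("node", "predator_removal", "policy_on"))
  expect_equal(back$predator_removal, unname(res[[1]]$change),
               tolerance = 1e-6)
  # with CIs present each scenario gains lower/upper columns
  res[[1]]$ci_low <- res[[1]]$change - 0.5
  res[[1]]$ci_high <- res[[1]]$change + 0.5
  df2 <- write_predictions(res[[1]], path)
  expect_equal(names(df2),
               c("node", "predator_removal", "predator_removal.lower",
                 "predator_removal.upper"))
  expect_error(write_predictions(list(), tempfile()), "no results")
})
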