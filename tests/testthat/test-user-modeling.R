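test_that("mean pooling is the component-wise average", {
  expect_equal(aggregateUserEmbedding(rbind(c(1, 1), c(3, 3))), c(2, 2))
  v <- c(0.3, -1, 2)
  expect_equal(aggregateUserEmbedding(v), v)          # single tweet
  expect_equal(aggregateUserEmbedding(rbind(v, v, v)), v)  # duplication
  expect_error(aggregateUserEmbedding(matrix(0, 0, 3)), "no tweets")
})

test_that("pooling is order-invariant and stays in the convex hull", {
  set.seed(4)
  m <- matrix(rnorm(15), 5, 3)
  expect_equal(aggregateUserEmbedding(m),
               aggregateUserEmbedding(m[sample(5), ]))
  u <- aggregateUserEmbedding(m)
  expect_true(all(u >= apply(m, 2, min) - 1e-12))
  expect_true(all(u <= apply(m, 2, max) + 1e-12))
})

test_that("per-user pooling groups tweets correctly", {
  emb <- rbind(c(1, 1), c(3, 3), c(10, 0))
  rownames(emb) <- c("t1", "t2", "t3")
  out <- poolUserEmbeddings(emb, c("ua", "ua", "ub"))
  expect_equal(out$embeddings["ua", ], c(2, 2))
  expect_equal(out$embeddings["ub", ], c(10, 0))
  expect_equal(out$nTweets, c(ua = 2L, ub = 1L))
})

test_that("profile keywords label politically explicit users", {
  lex <- usPartyLexicon()
  expect_equal(classifyProfile("Progressive mom. Vote!", lex), "Democrat")
  expect_equal(classifyProfile("I post about gardening", lex), "none")
  expect_equal(classifyProfile("conservative democrat", lex), "ambiguous")
})

test_that("keyword matching is case-, punctuation- and boundary-aware", {
  lex <- usPartyLexicon()
  expect_equal(classifyProfile("TRUMP 2020!!!", lex), "Republican")
  expect_equal(classifyProfile("  #Biden  ", lex), "Democrat")
  expect_equal(classifyProfile("I raise gophers", lex), "none")  # no 'gop'
  expect_equal(classifyProfile("the GOP agenda", lex), "Republican")

  ca <- canadaPartyLexicon()
  expect_equal(classifyProfile("Proud New Democratic Party member", ca), "NDP")
  expect_equal(classifyProfile("People's Party forever", ca), "PPC")
  # multi-word phrases only fire as contiguous runs
  expect_equal(classifyProfile("green energy party planner", ca), "none")
})

test_that("classification is deterministic and vectorized", {
  lex <- usPartyLexicon()
  profiles <- c("biden fan", "gardening", "gop and proud", "biden fan")
  out <- classifyProfile(profiles, lex)
  expect_equal(out, c("Democrat", "none", "Republican", "Democrat"))
})

test_that("activity filter keeps users at or above the threshold", {
  counts <- c(a = 10, b = 9, c = 25, d = 1)
  expect_setequal(activityFilter(counts, 10), c("a", "c"))
  expect_setequal(activityFilter(counts, 1), c("a", "b", "c", "d"))
  expect_error(activityFilter(counts, 0))
})

test_that("party families merge and unmapped parties drop", {
  ca <- canadaPartyLexicon()
  lab <- c(u1 = "NDP", u2 = "PPC", u3 = "Bloc Quebecois", u4 = "LPC",
           u5 = "CPC", u6 = "GPC")
  fam <- mergePartyFamilies(lab, ca)
  expect_equal(fam[["u1"]], "LPF")
  expect_equal(fam[["u2"]], "RPF")
  expect_equal(fam[["u4"]], "LPF")
  expect_equal(fam[["u5"]], "RPF")
  expect_equal(fam[["u6"]], "LPF")
  expect_false("u3" %in% names(fam))
})

test_that("label propagation recovers planted families on separable data", {
  pop <- gaussianPop(60, d = 8, delta = 6, sigma = 1, seed = 17)
  emb <- embeddingMatrix(pop)
  truth <- setNames(as.character(partyLabels(pop)), userIds(pop))
  set.seed(99)
  seedIds <- unlist(lapply(split(names(truth), truth),
                           function(ids) sample(ids, 15)))
  out <- propagateLabels(truth[seedIds], emb,
                         classifier = linearActivityClassifier(seed = 1))
  held <- setdiff(names(truth), seedIds)
  acc <- mean(out[held] == truth[held])
  expect_gte(acc, 0.95)
  # seed labels pass through unchanged
  expect_identical(out[seedIds], truth[seedIds])
})

test_that("propagation accuracy does not fall as separation grows", {
  accAt <- function(delta) {
    accs <- vapply(1:3, function(s) {
      pop <- gaussianPop(40, d = 8, delta = delta, sigma = 1, seed = 50 + s)
      emb <- embeddingMatrix(pop)
      truth <- setNames(as.character(partyLabels(pop)), userIds(pop))
      set.seed(s)
      seedIds <- unlist(lapply(split(names(truth), truth),
                               function(ids) sample(ids, 12)))
      out <- propagateLabels(truth[seedIds], emb)
      held <- setdiff(names(truth), seedIds)
      mean(out[held] == truth[held])
    }, numeric(1))
    mean(accs)
  }
  expect_lte(accAt(0.5), accAt(4) + 0.02)
})

test_that("propagation demands enough seeds per family", {
  pop <- gaussianPop(30, d = 4, delta = 4, seed = 23)
  emb <- embeddingMatrix(pop)
  truth <- setNames(as.character(partyLabels(pop)), userIds(pop))
  few <- truth[c(1:12, 31:35)]  # second family below the minimum
  expect_error(propagateLabels(few, emb), "insufficient seeds")
})

test_that("voter records match on county plus exact name", {
  users <- data.frame(
    user_id = c("u1", "u2", "u3", "u4", "u5"),
    display_name = c("Jane Doe", "Jane Doe", "Al Green", "Bob Q. Smith",
                     "Eve \U0001F600 Jones"),
    county = c("X", "Y", "X", "X", "X"),
    stringsAsFactors = FALSE)
  records <- data.frame(
    name = c("Jane Doe", "Jane Doe", "Jane Doe", "Al Green",
             "Bob Q Smith", "Eve Jones"),
    county = c("X", "Y", "Y", "X", "X", "X"),
    party = c("Democrat", "Republican", "Democrat", "Green",
              "Republican", "Democrat"),
    stringsAsFactors = FALSE)
  out <- matchVoterRecords(users, records)
  expect_equal(out[["u1"]], "Democrat")        # unique county+name match
  expect_false("u2" %in% names(out))           # two records in county Y
  expect_false("u3" %in% names(out))           # non-major party
  expect_equal(out[["u4"]], "Republican")      # first+middle+last form
  expect_equal(out[["u5"]], "Democrat")        # emoji stripped
})
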