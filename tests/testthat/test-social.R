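test_that("pronoun densities count inventory members over total tokens", {
  d <- pronoun_densities(c("we", "love", "our", "garden"))
  expect_equal(unname(d["first_plural"]), 0.5)
  expect_equal(unname(d["first_singular"]), 0)
  expect_equal(sum(pronoun_densities(c("just", "plain", "words"))), 0)
  # 20-token fixture with 3 "I", 2 "we", 1 "they"
  toks <- c(rep("i", 3), rep("we", 2), "they", rep("word", 14))
  d2 <- pronoun_densities(toks)
  expect_equal(unname(d2), c(0.15, 0.10, 0.05))
  d0 <- pronoun_densities(character(0))
  expect_true(all(d0 == 0))
  expect_equal(attr(d0, "flags"), "degenerate")
})

test_that("second-person pronouns are excluded and classes stay disjoint", {
  inv <- pronoun_inventory()
  expect_equal(sum(pronoun_densities(c("you", "your", "yours"))), 0)
  all_words <- unlist(inv)
  expect_equal(anyDuplicated(all_words), 0L)
  # densities over disjoint classes can never exceed 1
  d <- pronoun_densities(c(inv$first_singular, inv$first_plural, inv$third))
  expect_lte(sum(d), 1)
})

test_that("relationship counting is pure dictionary lookup by category", {
  lex <- test_lexicons$relationships
  c1 <- count_relationships("my husband and my daughter", lex)
  expect_equal(unname(c1["spouse"]), 1L)
  expect_equal(unname(c1["children"]), 1L)
  expect_equal(attr(c1, "total"), 2L)
  # co-referent mentions each count (the acknowledged overestimate)
  c2 <- count_relationships("I have children. A son and a daughter.", lex)
  expect_equal(unname(c2["children"]), 3L)
  c3 <- count_relationships("nothing relevant here at all", lex)
  expect_length(c3, 0)
  expect_equal(attr(c3, "total"), 0L)
})

test_that("plural s-stripping folds sons/daughters onto the lexicon", {
  lex <- c(son = "children", daughter = "children")
  cc <- count_relationships("my sons and daughters", lex)
  expect_equal(unname(cc["children"]), 2L)
})

test_that("doubling a response doubles every relationship count", {
  lex <- test_lexicons$relationships
  text <- "my wife, my son, my son and an old friend"
  once <- count_relationships(text, lex)
  twice <- count_relationships(paste(text, text), lex)
  expect_equal(as.integer(twice[names(once)]), 2L * as.integer(once))
})

test_that("counts are invariant to sentence order", {
  lex <- test_lexicons$relationships
  a <- count_relationships("My wife helps me. My son visits.", lex)
  b <- count_relationships("My son visits. My wife helps me.", lex)
  expect_equal(a[sort(names(a))], b[sort(names(b))])
})

test_that("communication profile maps phrases to frequency and modes", {
  p <- communication_profile("I call my son every day", test_lexicons)
  expect_equal(p$frequency_per_month, 30)
  expect_true("phone" %in% p$modes)
  p2 <- communication_profile("we email once a month", test_lexicons)
  expect_equal(p2$frequency_per_month, 1)
  expect_true("email" %in% p2$modes)
  # several frequency phrases: the maximum (most frequent contact) wins
  p3 <- communication_profile(
    "we talk every day but we visit once a week", test_lexicons)
  expect_equal(p3$frequency_per_month,
               max(test_lexicons$comm_frequency[c("every day", "once a week")]))
  expect_equal(p3$frequency_per_month, 30)
  # no frequency phrase at all: missing, not zero
  p4 <- communication_profile("we stay in touch", test_lexicons)
  expect_true(is.na(p4$frequency_per_month))
  expect_equal(attr(p4$frequency_per_month, "flags"), "frequency_missing")
})

test_that("none-understood detection needs negation without relationship words", {
  expect_true(detect_none_understood("No, nobody really understands me",
                                     test_lexicons$none_understood,
                                     test_lexicons$relationships))
  expect_false(detect_none_understood("My wife understands me",
                                      test_lexicons$none_understood,
                                      test_lexicons$relationships))
  expect_false(detect_none_understood("Nobody but my daughter",
                                      test_lexicons$none_understood,
                                      test_lexicons$relationships))
})

test_that("social profile assembles totals and both pronoun scopes", {
  tr <- fixture_transcript()
  located <- localize_responses(tr, test_templates)
  prof <- social_profile(tr, located, test_lexicons)
  expect_equal(prof$important_total, sum(prof$important_counts))
  expect_equal(prof$understood_total, sum(prof$understood_counts))
  expect_false(prof$none_understood)
  expect_equal(prof$comm_frequency_per_month, 30)
  expect_true(all(c("phone", "email") %in% prof$modes))
  expect_true(all(prof$pronoun_density$whole_transcript >= 0))
  expect_true(sum(prof$pronoun_density$whole_transcript) <= 1)
})
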