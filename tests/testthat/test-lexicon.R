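test_that("tokenizer lowercases, strips URLs/mentions/hashtag marks", {
  expect_identical(tokenize("Je suis à #Paris http://t.co/x @ami"),
                   c("je", "suis", "à", "paris"))
  expect_identical(tokenize("Liberté, Égalité!"),
                   c("liberté", "égalité"))
  expect_identical(tokenize(""), character(0))
  expect_identical(tokenize("123 456"), character(0))
  expect_identical(tokenize("l'égalité d'abord"),
                   c("l'égalité", "d'abord"))
  # vectorized form returns one token vector per text
  expect_identical(tokenize_all(c("Un chat", "")),
                   list(c("un", "chat"), character(0)))
})

test_that("entry matching: literals exact, stems by prefix", {
  expect_true(matches("solidar*", "solidarité"))
  expect_false(matches("ami", "amis"))
  expect_true(matches("ami*", "ami"))
  expect_true(matches("ami", "ami"))
  expect_false(matches("solidar*", "solide"))
})

test_that("indicator_fraction follows the count/total contract", {
  lex <- toy_lexicon()
  toks <- c("je", "suis", "content", rep("et", 7))  # 1 of 10 matches
  expect_equal(indicator_fraction(toks, lex), 0.1)
  expect_true(is.na(indicator_fraction(character(0), lex)))
  expect_equal(indicator_fraction(c("joie", "heureux", "contente"),
                                  lex), 1.0)
  # a token matching several entries counts once
  lex2 <- lexicon("x", c("content*", "co*"))
  expect_equal(indicator_fraction(c("content", "autre"), lex2), 0.5)
})

test_that("scoring invariants: bounds, dilution, case-insensitivity", {
  lex <- demo_lexicons("negemo")[[1]]
  set.seed(42)
  pool <- c(demo_filler_words(), "peur", "colère", "tristesse")
  for (i in 1:25) {
    toks <- sample(pool, sample(1:30, 1), replace = TRUE)
    f <- indicator_fraction(toks, lex)
    expect_true(f >= 0 && f <= 1)
    if (f > 0) {
      diluted <- indicator_fraction(c(toks, "et"), lex)
      expect_lt(diluted, f)
    }
    txt <- paste(toks, collapse = " ")
    expect_equal(indicator_fractions(toupper(txt), lex),
                 indicator_fractions(txt, lex))
  }
})

test_that("indicator_fractions agrees with per-text scoring", {
  lex <- demo_lexicons("social")[[1]]
  texts <- c("mes amis et ma famille", "", "le train du matin",
             "solidarité ensemble")
  expect_equal(indicator_fractions(texts, lex),
               vapply(tokenize_all(texts),
                      indicator_fraction, 0.0, lex = lex))
})

test_that(".dic parsing handles categories, stems and bad input", {
  path <- withr::local_tempfile(fileext = ".dic")
  writeLines(c("%", "1\tposemo", "%",
               "heureux\t1", "content*\t1"), path)
  lx <- read_liwc_dic(path)
  expect_length(lx, 1L)
  expect_identical(lx$posemo$literals, "heureux")
  expect_identical(lx$posemo$stems, "content")

  writeLines(c("%", "1\tposemo", "%", "triste\t99"), path)
  expect_error(read_liwc_dic(path), "unknown category id 99")

  writeLines(c("%", "1\tposemo", "2\tnegemo", "%", "heureux\t1"), path)
  expect_error(read_liwc_dic(path), "empty .dic category: negemo")

  writeLines(c("heureux\t1"), path)
  expect_error(read_liwc_dic(path), "malformed")
})

test_that(".dic round-trip is the identity on entry sets", {
  path <- withr::local_tempfile(fileext = ".dic")
  lx <- demo_lexicons()
  write_liwc_dic(lx, path)
  back <- read_liwc_dic(path)
  expect_identical(names(back), names(lx))
  for (nm in names(lx))
    expect_setequal(lexicon_entries(back[[nm]]),
                    lexicon_entries(lx[[nm]]))
})

test_that("plain JSON lexicon format round-trips", {
  path <- withr::local_tempfile(fileext = ".json")
  lx <- demo_lexicons(c("posemo", "values"))
  write_lexicon_json(lx, path)
  back <- read_lexicon_json(path)
  expect_setequal(lexicon_entries(back$values),
                  lexicon_entries(lx$values))
})

test_that("validation percent increase matches its definition", {
  lex <- toy_lexicon()
  a <- c("joie rien rien rien rien rien rien rien rien rien",  # 0.10
         "rien rien rien rien rien rien rien rien rien rien")  # 0.00
  b <- "joie rien rien rien rien rien rien rien rien rien"     # 0.10
  expect_equal(validate_percent_increase(a, b, lex),
               100 * (0.05 / 0.10 - 1))
  # +110% example: mean_a = 0.021, mean_b = 0.010
  a2 <- c("joie rien rien rien rien rien rien rien rien rien",   # 0.10
          "joie joie rien rien rien rien rien rien rien rien",   # 0.20
          rep("rien rien rien rien rien rien rien rien rien rien",
              8))                                                # 8 x 0
  # mean_a2 = 0.30 / 10 = 0.03; scale b for a 110% increase
  b2 <- c("joie rien rien rien rien rien rien rien rien rien",
          rep("rien rien rien rien rien rien rien rien rien rien", 6))
  # mean_b2 = 0.1 / 7
  expect_equal(validate_percent_increase(a2, b2, lex),
               100 * (0.03 / (0.1 / 7) - 1))
  expect_equal(validate_percent_increase(a, a, lex), 0)
  expect_error(validate_percent_increase(a, c("rien du tout"), lex),
               "undefined baseline")
  expect_error(validate_percent_increase(character(0), b, lex),
               "non-empty")
})

test_that("lexicon constructor enforces invariants", {
  expect_error(lexicon("x", character(0)), "non-empty")
  lx <- lexicon("x", c("Ami", "AMI*"))
  expect_identical(lx$stems, "ami")      # lowercased
  expect_length(lx$literals, 0L)         # literal subsumed by own stem
})
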