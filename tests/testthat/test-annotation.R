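regA <- replicon_set("chr", 1000, ori = 0, ter = 500)
regBig <- replicon_set("chr", 100000, ori = 0, ter = 50000)

gene_df <- function(start, end, strand, replicon = "chr") {
  data.frame(replicon = replicon, start = start, end = end, strand = strand,
             gene_id = sprintf("g%d", seq_along(start)),
             stringsAsFactors = FALSE)
}

pk <- function(start, end, replicon = "chr") {
  data.frame(replicon = replicon, start = start, end = end,
             stringsAsFactors = FALSE)
}

test_that("context classification covers the definitional cases", {
  genes1 <- gene_df(100, 400, "+")
  expect_equal(classify_context(pk(150, 300), genes1, regBig), "CDS")

  genes2 <- gene_df(c(100, 600), c(400, 900), c("+", "+"))
  expect_equal(classify_context(pk(450, 550), genes2, regBig), "IR")
  expect_equal(classify_context(pk(350, 650), genes2, regBig), "CDS5_IR_CDS3")

  # minus-strand downstream gene: its coordinate-left end is its 3' end
  genes3 <- gene_df(c(100, 600), c(400, 900), c("+", "-"))
  expect_equal(classify_context(pk(450, 700), genes3, regBig), "IR_3CDS")
  # plus-strand downstream gene: same interval covers a 5' end
  expect_equal(classify_context(pk(450, 700), genes2, regBig), "IR_5CDS")
  # upstream gene's 3' end on plus strand
  expect_equal(classify_context(pk(350, 550), genes2, regBig), "IR_3CDS")

  # peak spanning a full gene is OTHER, as are three genes or two
  # same-polarity ends
  expect_equal(classify_context(pk(50, 450), genes1, regBig), "OTHER")
  genes4 <- gene_df(c(100, 600), c(400, 900), c("-", "+"))  # two 5' ends
  expect_equal(classify_context(pk(350, 650), genes4, regBig), "OTHER")
  genes5 <- gene_df(c(100, 300, 500), c(200, 400, 700), c("+", "+", "+"))
  expect_equal(classify_context(pk(150, 650), genes5, regBig), "OTHER")
})

test_that("context classification works across the seam", {
  L <- 1000
  reg <- replicon_set("chr", L, ori = 200, ter = 700)
  genes <- gene_df(c(900, 100), c(980, 300), c("+", "+"))
  # wrapped peak covering g1's 3' end, the seam IR, and g2's 5' end
  expect_equal(classify_context(pk(950, 1150), genes, reg), "CDS5_IR_CDS3")
  # wrapped peak inside a wrapped... peak fully inside gene near seam
  genes2 <- gene_df(850, 1000, "+")
  expect_equal(classify_context(pk(900, 960), genes2, reg), "CDS")
})

test_that("relative gene position is strand-aware", {
  genes <- gene_df(0, 1000, "+")
  regK <- replicon_set("chr", 10000, ori = 5000, ter = 9000)
  expect_equal(relative_position_in_gene(pk(450, 550), genes[1, ], regK), 0.5)
  expect_equal(relative_position_in_gene(pk(875, 925), genes[1, ], regK), 0.9)
  genesm <- gene_df(0, 1000, "-")
  expect_equal(relative_position_in_gene(pk(875, 925), genesm[1, ], regK), 0.1)
})

test_that("fork_direction matches the stated arcs and the walker oracle", {
  expect_equal(fork_direction(250, regA[1, ]), "CW")
  expect_equal(fork_direction(750, regA[1, ]), "CCW")
  expect_equal(fork_direction(0, regA[1, ]), "AMBIGUOUS")
  expect_equal(fork_direction(500, regA[1, ]), "AMBIGUOUS")

  # oracle: walk from ori in both directions until ter; whichever walker
  # reaches the position first owns it
  walker <- function(p, L, ori, ter) {
    if (p == ori || p == ter) return("AMBIGUOUS")
    cw <- ori; ccw <- ori
    repeat {
      if (cw != ter) {
        cw <- (cw + 1) %% L
        if (cw == p) return("CW")
      }
      if (ccw != ter) {
        ccw <- (ccw - 1) %% L
        if (ccw == p) return("CCW")
      }
    }
  }
  set.seed(19)
  for (i in 1:400) {
    L <- sample(10:300, 1)
    ori <- sample.int(L, 1) - 1
    ter <- (ori + sample.int(L - 1, 1)) %% L
    p <- sample.int(L, 1) - 1
    reg <- replicon_set("r", L, ori, ter)
    expect_equal(fork_direction(p, reg[1, ]), walker(p, L, ori, ter),
                 info = sprintf("L=%d ori=%d ter=%d p=%d", L, ori, ter, p))
  }
})

test_that("fork orientation follows the lagging-template rule", {
  genes_p <- gene_df(200, 300, "+")
  # CW fork: plus strand is the lagging template
  expect_equal(assign_fork_orientation(pk(220, 280), genes_p, regA[1, ]),
               "LAG")
  genes_p2 <- gene_df(700, 800, "+")
  expect_equal(assign_fork_orientation(pk(720, 780), genes_p2, regA[1, ]),
               "LEAD")
  # no gene, mixed strands, and ori-spanning peaks are ND
  expect_equal(assign_fork_orientation(pk(220, 280), gene_df(600, 900, "+"),
                                       regA[1, ]), "ND")
  genes_mix <- gene_df(c(150, 250), c(240, 350), c("+", "-"))
  expect_equal(assign_fork_orientation(pk(200, 300), genes_mix, regA[1, ]),
               "ND")
  expect_equal(assign_fork_orientation(pk(950, 1050), gene_df(900, 1000, "+"),
                                       regA[1, ]), "ND")  # spans ori at 0
})

test_that("annotation is covariant under rotation and fork-geometry flips", {
  set.seed(20)
  L <- 50000
  reg <- replicon_set("chr", L, ori = 12000, ter = 37000)
  starts <- seq(500, L - 2000, by = 2500)
  genes <- gene_df(starts, starts + sample(800:1500, length(starts),
                                           replace = TRUE),
                   sample(c("+", "-"), length(starts), replace = TRUE))
  p_starts <- sample.int(L, 40, replace = TRUE) - 1
  peaks <- pk(p_starts, p_starts + 400)
  ann0 <- annotate_peaks(peaks, genes, reg)

  # joint rotation leaves every category and fork call unchanged
  k <- 23117
  reg_r <- replicon_set("chr", L, (12000 + k) %% L, (37000 + k) %% L)
  rot_iv <- function(df) {
    s <- (df$start + k) %% L
    transform(df, start = s, end = s + (df$end - df$start))
  }
  ann1 <- annotate_peaks(rot_iv(peaks), rot_iv(genes), reg_r)
  expect_equal(ann1$category, ann0$category)
  expect_equal(ann1$fork, ann0$fork)
  expect_equal(ann1$ori_distance, ann0$ori_distance)

  # flipping every gene strand and swapping ori<->ter preserves LAG/LEAD
  reg_f <- replicon_set("chr", L, ori = 37000, ter = 12000)
  genes_f <- transform(genes, strand = ifelse(strand == "+", "-", "+"))
  ann2 <- annotate_peaks(peaks, genes_f, reg_f)
  det <- ann0$fork %in% c("LAG", "LEAD") & ann2$fork %in% c("LAG", "LEAD")
  expect_gt(sum(det), 10)
  expect_equal(ann2$fork[det], ann0$fork[det])
})

test_that("replicon summaries conserve counts and close to 100 percent", {
  empty <- summarize_by_replicon(
    data.frame(replicon = character(), category = character(),
               fork = character()))
  expect_equal(nrow(empty$fork), 0)

  ann <- data.frame(replicon = "chr", category = "CDS", fork = "LAG",
                    stringsAsFactors = FALSE)[rep(1, 10), ]
  s <- summarize_by_replicon(ann)
  expect_equal(sum(s$fork$count), 10)
  expect_equal(s$fork$percent[s$fork$level == "LAG"], 100)
  expect_equal(sum(s$category$count), 10)
  expect_equal(sum(s$fork$percent), 100)
})
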