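trio <- c(sire = "SIRE", dam = "DAM", offspring = "AFF1")

test_that("trio AR filter matches the 64-combination truth table", {
    lv <- list(0L, 1L, 2L, NA_integer_)
    combos <- expand.grid(s = lv, d = lv, o = lv)
    doses <- cbind(SIRE = unlist(combos$s), DAM = unlist(combos$d),
                   AFF1 = unlist(combos$o))
    gm <- makeQuartetMatrix(doses)
    kept <- variantKeys(trioArFilter(gm, trio))
    truth <- vapply(seq_len(nrow(combos)), function(i)
        oracleTrioKeep(doses[i, 1], doses[i, 2], doses[i, 3]), TRUE)
    expect_setequal(kept, variantKeys(gm)[truth])
    expect_equal(length(kept), 1L)   # only het x het -> hom-alt survives
    ## permissive missing-genotype mode adds exactly the NA-containing rows
    keptPermissive <- variantKeys(trioArFilter(gm, trio, keepMissing = TRUE))
    hasNA <- apply(doses, 1, anyNA)
    expect_setequal(keptPermissive, variantKeys(gm)[truth | hasNA])
})

test_that("homozygous parents are non-Mendelian for an affected offspring", {
    gm <- makeQuartetMatrix(cbind(SIRE = c(1L, 2L, 0L), DAM = c(1L, 1L, 1L),
                                  AFF1 = c(2L, 2L, 2L)))
    kept <- trioArFilter(gm, trio)
    expect_equal(variantKeys(kept), variantKeys(gm)[1])
})

test_that("sex-chromosome contigs and absent samples are handled", {
    doses <- cbind(SIRE = c(1L, 1L), DAM = c(1L, 1L), AFF1 = c(2L, 2L))
    gr <- variantGRanges(c("chrA", "chrX"), c(10L, 10L), "A", "G",
                         exonic = TRUE, nonsynonymous = TRUE)
    gm <- genotypeMatrix(gr, doses)
    expect_equal(as.character(GenomicRanges::seqnames(
        variantRanges(trioArFilter(gm, trio)))), "chrA")
    expect_error(trioArFilter(gm, c(sire = "SIRE", dam = "DAM",
                                    offspring = "NOPE")), "absent")
})

test_that("trio intersection equals the set-operation oracle", {
    set.seed(11)
    doses <- matrix(1L, nrow = 30, ncol = 3,
                    dimnames = list(NULL, c("SIRE", "DAM", "AFF1")))
    gm <- makeQuartetMatrix(doses)
    for (rep in 1:20) {
        ia <- sort(sample(30, sample(0:30, 1)))
        ib <- sort(sample(30, sample(0:30, 1)))
        a <- gm[ia, ]; b <- gm[ib, ]
        got <- variantKeys(intersectTrios(a, b))
        expect_identical(got, intersect(variantKeys(a), variantKeys(b)))
        expect_setequal(got, variantKeys(intersectTrios(b, a)))
    }
    expect_identical(variantKeys(intersectTrios(gm, gm)), variantKeys(gm))
    expect_equal(nrow(intersectTrios(gm[1:5, ], gm[6:10, ])), 0L)
})

test_that("panel exclusion keys on homozygosity, not carrier status", {
    doses <- cbind(SIRE = c(1L, 1L, 1L), DAM = c(1L, 1L, 1L),
                   AFF1 = c(2L, 2L, 2L))
    gm <- makeQuartetMatrix(doses)
    panelDoses <- rbind(c(2L, 0L, 0L, 0L, 0L),      # hom in one dog
                        c(1L, 1L, 1L, 1L, 1L),      # het in five dogs
                        c(0L, 0L, 0L, 0L, 0L))
    colnames(panelDoses) <- sprintf("P%02d", 1:5)
    panel <- makeQuartetMatrix(panelDoses)
    colnames(panel) <- sprintf("P%02d", 1:5)
    kept <- variantKeys(panelPrivacyFilter(gm, panel))
    expect_setequal(kept, variantKeys(gm)[2:3])
})

test_that("panel filter equals a brute-force per-variant scan", {
    set.seed(19)
    for (rep in 1:20) {
        n <- 25
        doses <- matrix(2L, nrow = n, ncol = 1,
                        dimnames = list(NULL, "AFF1"))
        gr <- variantGRanges("chrA", seq_len(n) * 7L, "A", "G")
        s <- genotypeMatrix(gr, doses)
        ## panel covers a random subset of the variants
        idx <- sort(sample(n, sample(5:n, 1)))
        pg <- matrix(sample(c(0:2, NA), length(idx) * 6, replace = TRUE),
                     ncol = 6, dimnames = list(NULL, sprintf("P%d", 1:6)))
        panel <- genotypeMatrix(gr[idx], pg)
        got <- variantKeys(panelPrivacyFilter(s, panel))
        truth <- vapply(variantKeys(s), oraclePanelKeep, TRUE,
                        panelKeys = variantKeys(panel),
                        panelGeno = genotypes(panel))
        expect_setequal(got, variantKeys(s)[truth])
    }
})

test_that("cascade summary counts stages and enforces monotonicity", {
    doses <- cbind(SIRE = 1L, DAM = 1L, AFF1 = 2L, AFF2 = 2L)
    gm <- makeQuartetMatrix(doses)
    trios <- list(c(sire = "SIRE", dam = "DAM", offspring = "AFF1"),
                  c(sire = "SIRE", dam = "DAM", offspring = "AFF2"))
    res <- runCascade(gm, trios, panel = NULL)
    expect_true(all(res$summary$n == 1L))
    expect_equal(nrow(res$candidates), 1L)

    empty <- gm[0, ]
    resE <- runCascade(empty, trios, panel = NULL)
    expect_true(all(resE$summary$n == 0L))

    expect_error(summarizeCascade(list(a = gm[0, ], b = gm)),
                 "internal-consistency")
})

test_that("cascade recovers exactly the planted causal variant", {
    cfg <- simConfig(seed = 3)
    construct <- buildConstruct(cfg)
    hits <- 0L; extras <- 0L
    for (s in 1:10) {
        cfg2 <- simConfig(seed = 100 + s)
        sim <- simulateQuartetPanel(cfg2, construct)
        trios <- pedigreeTrios(sim$pedigree)
        res <- runCascade(sim$quartet, trios, sim$panel)
        keys <- variantKeys(res$candidates)
        if (sim$manifest$causal %in% keys) hits <- hits + 1L
        extras <- extras + (length(keys) - 1L)
    }
    expect_equal(hits, 10L)      # sensitivity 1
    expect_equal(extras, 0L)     # specificity 1
})

test_that("every filter output is a subset of its input", {
    cfg <- simConfig(seed = 5)
    construct <- buildConstruct(cfg)
    sim <- simulateQuartetPanel(cfg, construct)
    trios <- pedigreeTrios(sim$pedigree)
    res <- runCascade(sim$quartet, trios, sim$panel)
    stages <- res$stages
    allKeys <- variantKeys(sim$quartet)
    for (st in stages)
        expect_true(all(variantKeys(st) %in% allKeys))
    expect_true(all(diff(res$summary$n[
        !grepl("^AR_trio", res$summary$stage)]) <= 0))
})
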