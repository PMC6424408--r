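test_that("CDS extraction handles strand and exon concatenation", {
    ## plus strand, single exon: plain substring
    g1 <- Biostrings::DNAStringSet(c(ctg = "TTATGAAATGCTAAGG"))
    tm1 <- transcriptModel("TOY", "t1", "ctg", "+", 3, 14)
    expect_equal(extractCds(tm1, g1), "ATGAAATGCTAA")

    ## minus strand, two exons: reverse complement of the concatenation
    ## hand-computed: CDS ATGAAATGCTAA <- revcomp("TTAGC" + "ATTTCAT")
    sq <- paste0("GG", "TTAGC", "GGGG", "ATTTCAT", "AA")
    g2 <- Biostrings::DNAStringSet(c(ctg = sq))
    tm2 <- transcriptModel("TOY", "t2", "ctg", "-", c(3, 12), c(7, 18))
    expect_equal(extractCds(tm2, g2), "ATGAAATGCTAA")

    ## model errors and warnings
    tmBad <- transcriptModel("TOY", "t3", "ctg", "+", 3, 13)
    expect_error(extractCds(tmBad, g1), "divisible by 3")
    g3 <- Biostrings::DNAStringSet(c(ctg = "ATGTAAAAATGA"))
    tm3 <- transcriptModel("TOY", "t4", "ctg", "+", 1, 12)
    expect_warning(extractCds(tm3, g3), "internal stop")
})

test_that("genomic/coding projection is invertible and strand-aware", {
    sq <- paste0("GG", "TTAGC", "GGGG", "ATTTCAT", "AA")
    g <- Biostrings::DNAStringSet(c(ctg = sq))
    tm <- transcriptModel("TOY", "t2", "ctg", "-", c(3, 12), c(7, 18))
    for (cp in seq_len(cdsLength(tm)))
        expect_equal(TrioSeg:::.genomicToCds(tm, cdsToGenomic(tm, cp)), cp)
})

test_that("coding names use the 3'-most repeat anchor and both dialects", {
    ## CDS with a C5 run at c.7..11, insertion placed mid-run
    cds <- "ATGTTACCCCCGAAATGA"            # M L P P K * with C5 run 7..11
    w <- wrapCds(cds)
    v <- variantGRanges("ctg", 8, "C", "CC")
    cv <- projectToCds(v, w$tm, w$genome)
    expect_true(cv$coding)
    expect_equal(cv$cName, "c.11insC")
    expect_equal(projectToCds(v, w$tm, w$genome, dialect = "hgvs")$cName,
                 "c.11_12insC")
    ## SNV naming
    s <- variantGRanges("ctg", 5, "T", "G")
    expect_equal(projectToCds(s, w$tm, w$genome)$cName, "c.5T>G")
    ## intronic / outside variants signal non-coding, not an error
    g2 <- Biostrings::DNAStringSet(c(ctg = paste0(cds, "TTTT")))
    tm2 <- transcriptModel("TOY", "t", "ctg", "+", 1, nchar(cds))
    out <- projectToCds(variantGRanges("ctg", nchar(cds) + 2L, "T", "A"),
                        tm2, g2)
    expect_false(out$coding)
})

test_that("an SNV at coding position 7244 is named c.7244C>T", {
    set.seed(7)
    cds <- makeRandomCds(2415)                      # 7248 nt incl stop
    cds <- paste0(substr(cds, 1, 7242), "ACA", substr(cds, 7246, nchar(cds)))
    w <- wrapCds(cds)
    v <- variantGRanges("ctg", 7244, "C", "T")
    cv <- projectToCds(v, w$tm, w$genome)
    expect_equal(cv$cName, "c.7244C>T")
    pc <- callConsequence(v, w$tm, w$genome)
    expect_equal(consequenceKind(pc), "missense")
})

test_that("wobble substitutions are synonymous with unchanged lengths", {
    cds <- "ATGCTTAAATAA"                            # M L K *
    w <- wrapCds(cds)
    v <- variantGRanges("ctg", 6, "T", "G")          # CTT -> CTG, both Leu
    pc <- callConsequence(v, w$tm, w$genome)
    expect_equal(consequenceKind(pc), "synonymous")
    tmv <- truncationMetrics(pc)
    expect_equal(tmv$mutLength, tmv$wtLength)
    expect_equal(tmv$residuesLost, 0L)
})

test_that("consequence caller agrees with brute-force re-translation", {
    set.seed(101)
    nBad <- 0
    for (rep in 1:220) {
        n <- sample(20:60, 1)
        cds <- makeRandomCds(n)
        w <- wrapCds(cds)
        pos <- sample(4:(nchar(cds) - 4L), 1)
        b <- substr(cds, pos, pos)
        kindDraw <- sample(c("ins", "del", "snv"), 1)
        if (kindDraw == "ins") {
            ref <- b; alt <- paste0(b, sample(c("A", "C", "G", "T"), 1))
        } else if (kindDraw == "del") {
            ref <- substr(cds, pos, pos + 1L); alt <- b
        } else {
            ref <- b; alt <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }
        v <- variantGRanges("ctg", pos, ref, alt)
        pc <- suppressWarnings(callConsequence(v, w$tm, w$genome))
        or <- oracleConsequence(cds, pos, ref, alt)
        ok <- identical(consequenceKind(pc), or$kind) &&
            identical(truncationMetrics(pc)$mutLength,
                      as.integer(or$mutLength)) &&
            identical(truncationMetrics(pc)$stopPosition,
                      as.integer(or$stopPosition))
        if (!ok) nBad <- nBad + 1
    }
    expect_equal(nBad, 0)
})

test_that("in-frame deletions leave downstream residues untouched", {
    set.seed(55)
    for (rep in 1:25) {
        cds <- makeRandomCds(30)
        w <- wrapCds(cds)
        pos <- sample(seq(4, 80, by = 3), 1)         # codon-aligned
        ref <- substr(cds, pos, pos + 3L)
        v <- variantGRanges("ctg", pos, ref, substr(ref, 1, 1))
        pc <- suppressWarnings(callConsequence(v, w$tm, w$genome))
        expect_equal(consequenceKind(pc), "inframe_indel")
        wt <- oracleTranslate(cds)
        codon <- (pos + 2L) %/% 3L
        mutTail <- oracleTranslate(paste0(substr(cds, 1, pos),
                                          substr(cds, pos + 4, nchar(cds))))
        ## residues beyond the deleted codon equal the shifted wild type
        expect_equal(mutTail[(codon + 1L):length(mutTail)],
                     wt[(codon + 2L):length(wt)])
    }
})

test_that("a variant and its mirrored minus-strand twin agree", {
    set.seed(77)
    for (rep in 1:20) {
        cds <- makeRandomCds(25)
        pad5 <- paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
        pad3 <- paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
        sq <- paste0(pad5, cds, pad3)
        L <- nchar(sq)
        gPlus <- Biostrings::DNAStringSet(c(ctg = sq))
        tmPlus <- transcriptModel("TOY", "t", "ctg", "+", 11, 10 + nchar(cds))
        gMinus <- Biostrings::DNAStringSet(c(ctg = as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(sq)))))
        tmMinus <- transcriptModel("TOY", "t", "ctg", "-",
                                   L - (10 + nchar(cds)) + 1L, L - 11L + 1L)
        pos <- sample(15:(10 + nchar(cds) - 5L), 1)
        b <- substr(sq, pos, pos)
        alt <- paste0(b, sample(c("A", "C", "G", "T"), 1))   # 1-bp insertion
        vPlus <- variantGRanges("ctg", pos, b, alt)
        rc <- function(x) as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(x)))
        ## mirrored twin: inserting N after pos on the + contig equals
        ## inserting revcomp(N) after (L - pos) on the flipped contig,
        ## anchored at base L - pos
        anchor <- L - pos
        ab <- substr(as.character(gMinus[[1]]), anchor, anchor)
        vMinus <- variantGRanges("ctg", anchor, ab,
                                 paste0(ab, rc(substr(alt, 2, 2))))
        pcPlus <- suppressWarnings(callConsequence(vPlus, tmPlus, gPlus))
        pcMinus <- suppressWarnings(callConsequence(vMinus, tmMinus, gMinus))
        expect_equal(consequenceKind(pcMinus), consequenceKind(pcPlus))
        expect_equal(proteinName(pcMinus), proteinName(pcPlus))
        expect_equal(truncationMetrics(pcMinus), truncationMetrics(pcPlus))
    }
})

test_that("protein names are deterministic across equivalent spellings", {
    cds <- "ATGTTACCCCCGAAATGA"
    w <- wrapCds(cds)
    names <- vapply(6:11, function(p) {
        b <- substr(cds, p, p)
        proteinName(callConsequence(
            variantGRanges("ctg", p, b, paste0(b, "C")), w$tm, w$genome))
    }, "")
    expect_length(unique(names), 1L)
})

test_that("destroying the start codon is reported as start_lost", {
    cds <- "ATGCTTAAATAA"
    w <- wrapCds(cds)
    v <- variantGRanges("ctg", 1, "A", "C")
    pc <- suppressWarnings(callConsequence(v, w$tm, w$genome))
    expect_equal(consequenceKind(pc), "start_lost")
    expect_equal(proteinName(pc), "p.M1?")
})
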