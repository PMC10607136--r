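test_that("intensity matrices round-trip through disk in both orientations", {
    se <- randomSE(5, 3, seed = 7)
    for (orient in c("samples_in_rows", "antigens_in_rows")) {
        path <- withr::local_tempfile(fileext = ".tsv")
        writeIntensityMatrix(se, path, orientation = orient)
        back <- readIntensityMatrix(path, orientation = orient)
        expect_equal(mfi(back), mfi(se), tolerance = 1e-12)
        expect_identical(rownames(back), rownames(se))
        expect_identical(colnames(back), colnames(se))
    }
    # csv dialect too
    path <- withr::local_tempfile(fileext = ".csv")
    writeIntensityMatrix(se, path)
    expect_equal(mfi(readIntensityMatrix(path)), mfi(se), tolerance = 1e-12)
})

test_that("a small table reads with the expected shape", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c(",AG1,AG2", "S1,10,20", "S2,5,8", "S3,1,2"), path)
    se <- readIntensityMatrix(path)
    expect_identical(dim(se), c(2L, 3L))   # antigens x samples
    expect_identical(colnames(se), c("S1", "S2", "S3"))
})

test_that("invalid intensity files are rejected with informative errors", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c(",AG1,AG2", "S1,10,NA", "S2,5,8"), path)
    expect_error(readIntensityMatrix(path), "S1.*AG2")
    writeLines(c(",AG1,AG2", "S1,10,3", "S1,5,8"), path)
    expect_error(readIntensityMatrix(path), "duplicate id.*S1")
    writeLines(c(",AG1,AG1", "S1,10,3", "S2,5,8"), path)
    expect_error(readIntensityMatrix(path), "duplicate id.*AG1")
    writeLines(c(",AG1,AG2", "S1,-3,4", "S2,5,8"), path)
    expect_error(readIntensityMatrix(path), "S1.*AG1")
})

test_that("sample metadata is validated and enum fallbacks behave", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("sample_id,group,timepoint,anca_serotype",
                 "s1,AAV,diagnosis,MPO",
                 "s2,HC,single,"), path)
    md <- readSampleMetadata(path)
    expect_identical(nrow(md), 2L)
    expect_identical(as.character(md$group), c("AAV", "HC"))
    expect_identical(as.character(md$phenotype[2]), "not_applicable")

    writeLines(c("sample_id,group", "s1,XYZ"), path)
    expect_error(readSampleMetadata(path), "AAV, GCA, PMR, HC")

    writeLines(c("sample_id,group,anca_serotype", "s1,AAV,weird"), path)
    expect_warning(md <- readSampleMetadata(path), "anca_serotype")
    expect_identical(as.character(md$anca_serotype), "unknown")

    writeLines(c("group", "AAV"), path)
    expect_error(readSampleMetadata(path), "sample_id")
})

test_that("a full two-group cohort's metadata survives a disk round trip", {
    se <- simulateCohort(studyPhaseConfig("phase2", seed = 3))
    path <- withr::local_tempfile(fileext = ".tsv")
    df <- as.data.frame(colData(se))
    df$organ_involvement <- ""
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    md <- readSampleMetadata(path)
    expect_identical(nrow(md), 294L)       # 126 AAV + 168 HC
    expect_identical(sum(md$group == "AAV"), 126L)
    expect_identical(sum(md$group == "HC"), 168L)
})

test_that("antigen annotation validates coordinates and warns on odd lengths", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("antigen_id,gene_symbol,uniprot_id,aa_start,aa_end",
                 "a1,KIF4A,O95239,376,461",
                 "a2,KIF15,Q9NS87,671,748"), path)
    an <- readAntigenAnnotation(path)
    expect_identical(nrow(an), 2L)
    writeLines(c("antigen_id,gene_symbol,uniprot_id,aa_start,aa_end",
                 "a1,G1,P1,10,15"), path)
    expect_warning(readAntigenAnnotation(path), "40-100")
    writeLines(c("antigen_id,gene_symbol,uniprot_id,aa_start,aa_end",
                 "a1,G1,P1,50,40"), path)
    expect_error(readAntigenAnnotation(path), "aa_start")
})

test_that("qcFilter excludes low-validity samples, reports, and is idempotent", {
    se <- randomSE(40, 10, seed = 2)
    m <- mfi(se)
    m[, 4] <- 0                      # dead sample
    bad <- SeroExperiment(m)
    filt <- qcFilter(bad, minValidFraction = 0.5)
    expect_identical(ncol(filt), 9L)
    expect_identical(qcExclusions(filt)$sample_id, "S004")

    clean <- qcFilter(se)
    expect_identical(ncol(clean), ncol(se))
    expect_identical(nrow(qcExclusions(clean)), 0L)

    twice <- qcFilter(filt, minValidFraction = 0.5)
    expect_identical(mfi(twice), mfi(filt))
    expect_identical(qcExclusions(twice), qcExclusions(filt))

    allzero <- SeroExperiment(matrix(0, 2, 2,
        dimnames = list(c("a1", "a2"), c("s1", "s2"))))
    expect_error(qcFilter(allzero), "every sample")
})

test_that("a corrupted sample in a 126-sample cohort is the one removed", {
    cfg <- simulationConfig(c(AAV = 126), nAntigens = 50, seed = 9)
    se <- simulateCohort(cfg)
    m <- mfi(se)
    m[seq_len(30), 17] <- 0          # 60% of antigens invalid in one sample
    filt <- qcFilter(SeroExperiment(m), minValidFraction = 0.9)
    expect_identical(ncol(filt), 125L)
    expect_identical(qcExclusions(filt)$sample_id, colnames(m)[17])
    exp_path <- withr::local_tempfile(fileext = ".jsonl")
    writeExclusionReport(filt, exp_path)
    rec <- jsonlite::fromJSON(readLines(exp_path)[1])
    expect_identical(rec$sample_id, colnames(m)[17])
})
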