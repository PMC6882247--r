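# Build a minimal valid record row; override any field via ...
make_record <- function(id, ...) {
  rec <- list(
    patient_id = id,
    neoadjuvant_chemotherapy = FALSE,
    previous_open_liver_resection = FALSE,
    lesion_type = "benign",
    lesion_size_cm = 2,
    resection_class = "minor",
    blood_loss_ml = 100,
    converted = FALSE,
    surrounding_damage = FALSE,
    transfusion = FALSE,
    operative_time_min = 120,
    pedicle_clamping = FALSE,
    clamping_total_min = 0,
    clavien_dindo = "none"
  )
  over <- list(...)
  rec[names(over)] <- over
  as.data.frame(rec, stringsAsFactors = FALSE)
}

# n records at a given difficulty level, n_ioc of them converted (an IOC).
# Factor settings chosen to pin the total score: low 0, moderate 4, high 6,
# extremely_high 15.
make_level_block <- function(prefix, n, n_ioc, level) {
  settings <- switch(level,
    low = list(),
    moderate = list(lesion_type = "malignant", lesion_size_cm = 4),
    high = list(lesion_type = "malignant", lesion_size_cm = 4,
                resection_class = "technically_major"),
    extremely_high = list(neoadjuvant_chemotherapy = TRUE,
                          previous_open_liver_resection = TRUE,
                          lesion_type = "malignant", lesion_size_cm = 6,
                          resection_class = "anatomically_major"))
  rows <- lapply(seq_len(n), function(i) {
    do.call(make_record, c(list(id = sprintf("%s%03d", prefix, i),
                                converted = i <= n_ioc), settings))
  })
  do.call(rbind, rows)
}

# The study-structured cohort: level counts 36/63/27/2 with IOC 0/6/15/2.
make_table3_cohort <- function() {
  df <- rbind(
    make_level_block("L", 36, 0, "low"),
    make_level_block("M", 63, 6, "moderate"),
    make_level_block("H", 27, 15, "high"),
    make_level_block("X", 2, 2, "extremely_high")
  )
  as_cohort(df, provenance = "file")
}

# Direct-summation Pearson chi-square oracle: sum (O - E)^2 / E.
chisq_oracle <- function(tab) {
  tab <- as.matrix(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Direct sum-of-squares one-way ANOVA oracle.
anova_oracle <- function(groups) {
  x <- unlist(groups)
  means <- vapply(groups, mean, numeric(1))
  ns <- vapply(groups, length, numeric(1))
  ssb <- sum(ns * (means - mean(x))^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1
  df2 <- length(x) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, df = c(df1, df2),
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Independent lookup oracle over the full 2x2x2x3x3 factor grid.
score_oracle_grid <- function() {
  grid <- expand.grid(
    chemo = c(FALSE, TRUE), prior = c(FALSE, TRUE),
    type = c("benign", "malignant"),
    size = c(2, 4, 6),                       # one representative per category
    class = c("minor", "technically_major", "anatomically_major"),
    stringsAsFactors = FALSE
  )
  grid$expected <- grid$chemo * 1 + grid$prior * 5 +
    (grid$type == "malignant") * 2 +
    c(`2` = 0, `4` = 2, `6` = 3)[as.character(grid$size)] +
    c(minor = 0, technically_major = 2, anatomically_major = 4)[grid$class]
  grid
}
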