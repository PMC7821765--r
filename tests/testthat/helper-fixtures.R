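# Fixture builders shared across the suite. Everything is generated in code;
# nothing is read from disk except files the tests themselves write.

PRED_FOR_CLASS <- c(I = "DDDDDDDDTT", II = "DDDDDTTTTT",
                    III = "DDTTTTTTTT", IV = "TTTTTTTTTT")

make_variants <- function(n, gene = "GENE001", effect = "nonsynonymous_snv",
                          pred = "TTTTTTTTTT", ids = sprintf("v%04d", seq_len(n)),
                          ...) {
  df <- data.frame(
    variant_id = ids,
    chrom = rep_len("1", n),
    pos = seq_len(n),
    ref = rep_len("A", n), alt = rep_len("G", n),
    gene = rep_len(gene, n), effect = rep_len(effect, n),
    pred = rep_len(pred, n),
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  variant_table(df)
}

make_patients <- function(ids, subgroup) {
  data.frame(patient_id = ids, subgroup = subgroup,
             age = 50, sex = "M", stringsAsFactors = FALSE)
}

# Build a cohort realizing an exact per-subgroup instance layout.
# spec: named list subgroup -> list(n = patients,
#   positives = c(I=, II_only=, III_only=), instances = c(I=,II=,III=,IV=))
# Instances beyond the one guaranteeing positivity go to already-positive
# patients; class IV instances go to the remaining (never-positive) patients
# first, spilling over to positive ones.
cohort_from_layout <- function(layout) {
  patients <- list(); geno <- list(); variants <- list()
  vid <- 0L
  new_variants <- function(k, cls) {
    if (k == 0L) return(character())
    ids <- sprintf("lv%05d", vid + seq_len(k))
    vid <<- vid + k
    variants[[length(variants) + 1L]] <<- make_variants(
      k, pred = PRED_FOR_CLASS[[cls]], ids = ids)
    ids
  }
  for (sg in names(layout)) {
    L <- layout[[sg]]
    pid <- sprintf("%s_p%03d", sg, seq_len(L$n))
    patients[[sg]] <- make_patients(pid, sg)
    nmax <- function(x) if (length(x)) max(x) else 0L
    a <- seq_len(L$positives[["I"]])                   # class-I positive
    b <- nmax(a) + seq_len(L$positives[["II_only"]])   # II but not I
    c_ <- nmax(c(a, b)) + seq_len(L$positives[["III_only"]])
    rest <- setdiff(seq_len(L$n), c(a, b, c_))
    give <- function(patient_idx, cls, k) {
      if (k == 0L) return()
      ids <- new_variants(k, cls)
      geno[[length(geno) + 1L]] <<- data.frame(
        patient_id = pid[patient_idx], variant_id = ids, zygosity = "het",
        stringsAsFactors = FALSE)
    }
    # one qualifying instance per newly-positive patient, surplus to the
    # first class-I-positive patient
    spread <- function(idx_first, extra_target, cls, total) {
      stopifnot(total >= length(idx_first))
      for (i in idx_first) give(i, cls, 1L)
      surplus <- total - length(idx_first)
      if (surplus > 0L) give(extra_target, cls, surplus)
    }
    spread(a, a[1L], "I", L$instances[["I"]])
    spread(b, a[1L], "II", L$instances[["II"]])
    spread(c_, a[1L], "III", L$instances[["III"]])
    # class IV instances: park them on never-positive patients when
    # available, else on the first patient (IV affects no threshold)
    iv_target <- if (length(rest) > 0L) rest[1L] else 1L
    give(iv_target, "IV", L$instances[["IV"]])
  }
  variants <- do.call(rbind, variants)
  class(variants) <- c("vt_variants", "data.frame")
  cohort(variants,
         do.call(rbind, patients),
         do.call(rbind, geno))
}

# The published molecular-burden layout (three case arms).
table3_layout <- list(
  CHD_VT = list(n = 23L, positives = c(I = 10L, II_only = 6L, III_only = 6L),
                instances = c(I = 13L, II = 18L, III = 58L, IV = 21L)),
  DCM_VT = list(n = 32L, positives = c(I = 10L, II_only = 14L, III_only = 7L),
                instances = c(I = 13L, II = 36L, III = 82L, IV = 28L)),
  iVT = list(n = 37L, positives = c(I = 20L, II_only = 10L, III_only = 6L),
             instances = c(I = 26L, II = 44L, III = 90L, IV = 27L))
)

# tiny deterministic config for fast simulated cohorts
small_config <- function(...) {
  sim_config(n_raw_variants = 400L,
             n_per_subgroup = c(CHD_VT = 8L, DCM_VT = 8L, iVT = 8L,
                                CONTROL = 10L),
             ...)
}
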