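# Encoded published reference results: the per-pair clonality
# comparisons and the per-gene clonal/private mutation spectrum from a
# mastectomy cohort study of LCIS clonal relatedness. These printed
# values serve as regression fixtures for the classification rule and
# the spectrum bookkeeping; the underlying raw data are not deposited,
# so only the printed numbers can be encoded.

#' Published lesion-pair comparison fixture
#'
#' All 65 within-patient lesion-pair comparisons meeting quality control
#' in a mastectomy cohort of women with LCIS: shared/total mutation
#' counts, the mutation-test and copy-number-test p-values, and the
#' printed verdict. P-values printed as "<0.001" are encoded as 0.0005
#' (any value below 0.001 yields identical verdicts under the
#' classification rule); `NA` marks a test that was not available for
#' the pair. `cdh1`/`pik3ca` flag a shared mutation in that gene.
#'
#' @return Data frame with columns `case`, `age`, `lesion_1`, `lesion_2`,
#'   `category`, `same_quadrant`, `size_cm`, `m` (shared mutations),
#'   `n_1`, `n_2` (profile totals), `p_mut`, `p_cn`, `diagnosis`,
#'   `cdh1`, `pik3ca`.
#' @export
#' @examples
#' tab <- lcis_pair_fixture()
#' table(tab$category, tab$diagnosis)
lcis_pair_fixture <- function() {
  txt <- "
case|age|lesion_1|lesion_2|same_quadrant|size_cm|m|n_1|n_2|p_mut|p_cn|diagnosis|cdh1|pik3ca
13|50|LCIS1|ILC|No|1.6|16|33|56|0.0005|0.002|Clonal|no|no
24|57|LCIS1|ILC|Yes|2.1|25|36|34|0.0005|0.0005|Clonal|yes|yes
24|57|LCIS2|ILC|No|NA|2|29|34|0.0005|NA|Clonal|no|no
28|60|LCIS|ILC|Yes|0.12|NA|NA|NA|NA|0.93|Independent|NA|NA
31|69|LCIS|ILC|Yes|1.5|NA|NA|NA|NA|0.31|Independent|NA|NA
33|65|LCIS|ILC|Yes|2.1|66|81|1015|0.0005|0.0005|Clonal|no|no
35|72|LCIS|ILC|Yes|4.7|NA|NA|NA|NA|0.0005|Clonal|NA|NA
38|73|LCIS2|ILC|Yes|NA|23|527|615|0.0005|0.54|Clonal|no|no
42|52|LCIS|ILC|Yes|2.3|56|119|109|0.0005|NA|Clonal|yes|yes
42|52|LCIS2|ILC|Yes|NA|NA|NA|NA|NA|0.01|Equivocal|NA|NA
43|41|LCIS|ILC|Yes|1.9|NA|NA|NA|NA|0.001|Clonal|NA|NA
45|55|LCIS|ILC|Yes|12.2|NA|NA|NA|NA|0.0005|Clonal|NA|NA
46|51|LCIS|ILC|Yes|4.5|0|46|15|1.0|NA|Independent|no|no
46|51|LCIS3|ILC|No|NA|0|37|15|1.0|NA|Independent|no|no
47|51|LCIS1|ILC|No|1.5|7|29|25|0.0005|0.0005|Clonal|yes|no
47|51|LCIS2|ILC|No|NA|7|22|25|0.0005|0.42|Clonal|yes|no
48|37|LCIS1|ILC|Yes|6.0|20|33|40|0.0005|0.0005|Clonal|yes|no
48|37|LCIS2|ILC|No|NA|1|22|40|0.03|0.10|Equivocal|no|no
52|50|LCIS|ILC|Yes|1.9|NA|NA|NA|NA|0.005|Clonal|NA|NA
52|50|LCIS2|ILC|Yes|NA|NA|NA|NA|NA|0.05|Independent|NA|NA
55|72|LCIS|ILC|Yes|1.3|6|31|36|0.0005|0.002|Clonal|no|yes
68|48|LCIS1|ILC|No|1.4|0|44|33|1.0|0.58|Independent|no|no
69|56|LCIS|ILC|Yes|3.0|18|56|31|0.0005|0.001|Clonal|yes|yes
73|44|LCIS1|ILC|Yes|0.5|0|26|42|1.0|NA|Independent|no|no
75|58|LCIS1|ILC|Yes|3.5|15|46|39|0.0005|NA|Clonal|yes|yes
26|54|LCIS|IDC|No|1.8|0|29|32|1.0|NA|Independent|no|no
47|51|LCIS1|IDC|No|1.0|1|29|30|0.02|0.35|Equivocal|no|no
47|51|LCIS2|IDC|No|NA|1|22|30|0.03|0.48|Equivocal|no|no
53|41|LCIS1|IDC|Yes|3.7|2|20|23|0.0005|0.40|Clonal|no|no
53|41|LCIS2|IDC|Yes|NA|1|15|23|0.02|0.62|Equivocal|no|no
74|61|LCIS1|IDC|Yes|0.75|0|32|34|1.0|0.50|Independent|no|no
74|61|LCIS2|IDC|No|NA|0|37|34|1.0|0.73|Independent|no|no
74|61|LCIS3|IDC|No|NA|3|42|34|0.0005|NA|Clonal|no|no
75|58|LCIS2|IDC|Yes|1.8|0|22|29|1.0|NA|Independent|no|no
4|44|LCIS1|LCIS2|No|NA|11|46|30|0.0005|NA|Clonal|no|no
5|67|LCIS1|LCIS2|No|NA|NA|NA|NA|NA|0.85|Independent|NA|NA
8|47|LCIS1|LCIS2|No|NA|9|34|25|0.0005|NA|Clonal|no|no
17|48|LCIS1|LCIS2|No|NA|13|26|27|0.0005|NA|Clonal|yes|no
19|43|LCIS1|LCIS2|No|NA|12|24|185|0.0005|NA|Clonal|no|no
24|57|LCIS1|LCIS2|No|NA|0|36|28|1.0|NA|Independent|no|no
38|73|LCIS1|LCIS2|Yes|NA|23|174|527|0.0005|NA|Clonal|no|no
46|51|LCIS|LCIS3|No|NA|5|46|37|0.0005|NA|Clonal|no|no
47|51|LCIS1|LCIS2|Yes|NA|8|29|22|0.0005|0.59|Clonal|yes|no
48|37|LCIS1|LCIS2|No|NA|0|33|22|1.0|0.59|Independent|no|no
52|50|LCIS|LCIS2|Yes|NA|13|28|34|0.0005|0.02|Clonal|yes|yes
53|41|LCIS1|LCIS2|Yes|NA|6|21|17|0.0005|0.005|Clonal|yes|no
59|47|LCIS|LCIS2|No|NA|12|31|26|0.0005|0.10|Clonal|yes|no
73|44|LCIS3|LCIS4|No|NA|0|14|11|1.0|NA|Independent|no|no
74|61|LCIS1|LCIS2|No|NA|0|32|37|1.0|0.02|Independent|no|no
74|61|LCIS1|LCIS3|No|NA|1|34|43|0.03|NA|Equivocal|no|no
74|61|LCIS2|LCIS3|No|NA|24|37|42|0.0005|NA|Clonal|yes|no
74|61|LCIS4|LCIS5|No|NA|14|41|47|0.0005|NA|Clonal|no|no
4|44|LCIS1|DCIS1|Yes|NA|15|46|703|0.0005|0.0005|Clonal|no|no
4|44|LCIS2|DCIS1|No|NA|10|30|703|0.0005|NA|Clonal|no|no
4|44|LCIS1|DCIS2|No|NA|13|46|24|0.0005|0.0005|Clonal|no|no
4|44|LCIS2|DCIS2|Yes|NA|8|30|24|0.0005|NA|Clonal|no|no
6|57|LCIS|DCIS|Yes|NA|6|50|75|0.0005|0.81|Clonal|no|no
16|62|LCIS|DCIS|No|NA|0|92|57|1.0|NA|Independent|no|no
26|54|LCIS|DCIS|No|NA|0|29|34|1.0|0.14|Independent|no|no
47|51|LCIS1|DCIS|Yes|NA|3|29|23|0.0005|0.71|Clonal|no|no
47|51|LCIS2|DCIS|Yes|NA|0|22|23|1.0|0.03|Independent|no|no
59|47|LCIS|DCIS|Yes|NA|6|31|31|0.0005|0.74|Clonal|no|no
59|47|LCIS2|DCIS|No|NA|2|26|31|0.003|0.67|Clonal|no|yes
68|48|LCIS1|DCIS|Yes|NA|8|44|33|0.0005|0.03|Clonal|no|no
75|58|LCIS2|DCIS|Yes|NA|0|22|38|1.0|NA|Independent|no|no"
  df <- utils::read.delim(text = txt, sep = "|", header = TRUE,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  hist2 <- sub("[0-9]+$", "", df$lesion_2)
  df$category <- paste0("LCIS-", hist2)
  df$cdh1 <- ifelse(is.na(df$cdh1), NA, df$cdh1 == "yes")
  df$pik3ca <- ifelse(is.na(df$pik3ca), NA, df$pik3ca == "yes")
  df[c("case", "age", "lesion_1", "lesion_2", "category", "same_quadrant",
       "size_cm", "m", "n_1", "n_2", "p_mut", "p_cn", "diagnosis",
       "cdh1", "pik3ca")]
}

#' Published per-gene mutation spectrum fixture
#'
#' The per-gene clonal/private mutation counts for the 23 most
#' frequently mutated genes among the sequenced cases of the same
#' cohort (hypermutated tumors and the outlier gene FSIP2 excluded in
#' the source tabulation). `total = clonal + private` distinct
#' (case, mutation) events per gene; `cases` is the number of cases
#' with at least one mutated tumor in the gene.
#'
#' @return Data frame `gene`, `total`, `cases`, `clonal`, `private`.
#' @export
lcis_spectrum_fixture <- function() {
  txt <- "
gene|total|cases|clonal|private
CDH1|24|16|11|13
PIK3CA|13|11|9|4
SPRR3|10|9|1|9
CBFB|10|8|7|3
GATA3|9|6|2|7
NBPF1|8|8|2|6
MUC12|7|5|1|6
KMT2C|6|6|1|5
MUC4|6|5|2|4
TCEAL3|6|4|5|1
MAP3K1|6|4|3|3
BCLAF1|5|5|0|5
HMCN1|5|5|0|5
TMPRSS13|5|4|1|4
REXO1L1|4|4|0|4
TDG|4|4|0|4
DDX11|4|4|1|3
ABCC5|4|4|0|4
MACF1|4|4|0|4
AGGF1|4|4|1|3
OR13C2|4|2|0|4
NASP|4|2|0|4
SERPINA3|4|2|0|4"
  utils::read.delim(text = txt, sep = "|", header = TRUE,
                    stringsAsFactors = FALSE, strip.white = TRUE)
}
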