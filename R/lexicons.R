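# Default cohort topic lexicons for the synthetic corpus generator.
# Message bodies are bags of short phrases drawn from the sender's
# sex-by-age-band pool; cohorts share a common core vocabulary (family
# planning, side effects, periods, pregnancy, sex) and add cohort-specific
# topics (e.g. safe days for young women, prostate and cancer for the
# oldest men -- the latter doubling as a planted cohort-specific signal for
# rank-recovery checks). Phrase repetition encodes sampling weight.

.core_en <- c(
  "what is the best method of family planning for me",
  "i want to know about family planning methods",
  "tell me about side effects of the pills",
  "what are the side effects of the injection",
  "can i get pregnant after taking the pill",
  "how do i prevent pregnancy",
  "i need information about contraception",
  "which contraception method is most effective",
  "my periods are irregular what should i do",
  "i have missed my period am i pregnant",
  "how much does the implant cost in ksh",
  "where can i get the emergency pill"
)

.core_sw <- c(
  "nataka kujua kuhusu uzazi wa mpango",
  "niambie kuhusu madhara ya vidonge",
  "je ninaweza kupata mimba baada ya sindano",
  "jinsi ya kuzuia mimba mapema",
  "nahitaji ushauri kuhusu njia za uzazi",
  "njia gani ya kupanga uzazi ni salama",
  "hedhi yangu haiji vizuri nifanye nini",
  "nimekosa hedhi je nina mimba",
  "dawa za dharura zinapatikana wapi",
  "bei ya kipandikizi ni ngapi",
  "madhara ya njia za uzazi ni yapi",
  "asante kwa msaada wako kuhusu afya"
)

.extras_en <- list(
  "female 15-19" = c(
    "which are my safe days after my period",
    "how do i count safe days in my cycle",
    "can i get pregnant during my safe days",
    "my period is late and i am worried",
    "does the emergency pill affect my periods"
  ),
  "female 20-24" = c(
    "i missed my period after unprotected sex",
    "does the emergency pill work after two days",
    "which pill is safe while breastfeeding",
    "can the injection delay my periods",
    "i want a method that does not affect my periods"
  ),
  "female 25-35" = c(
    "i want to conceive when should we try",
    "which family planning method suits a mother of two",
    "can i remove the implant to conceive",
    "how long after the injection can i conceive",
    "is the coil good for spacing children"
  ),
  "female 36+" = c(
    "what are signs of breast cancer",
    "how do i check my breasts for cancer",
    "what causes cervical cancer in women",
    "where can i screen for cervical cancer",
    "is family planning safe at my age"
  ),
  "male 15-19" = c(
    "is unprotected sex safe one time",
    "can a condom burst during sex",
    "how do i use a condom correctly",
    "can kissing transmit hiv",
    "does withdrawal prevent pregnancy during sex"
  ),
  "male 20-24" = c(
    "can condoms prevent hiv completely",
    "is oral sex safe from infection",
    "my girlfriend missed her period after sex",
    "how soon can an hiv test detect the virus",
    "where can i get free condoms"
  ),
  "male 25-35" = c(
    "which family planning method is best for my wife",
    "does vasectomy affect performance",
    "how can we space our children",
    "can stress lower fertility in men",
    "what causes low sperm count"
  ),
  "male 36+" = c(
    "what are symptoms of prostate cancer",
    "how is prostate cancer detected early",
    "is prostate screening painful",
    "at what age should i test my prostate",
    "can prostate problems affect urination",
    "what causes prostate enlargement in men",
    "does prostate cancer run in families",
    "what raises the risk of cancer in men"
  )
)

.extras_sw <- list(
  "female 15-19" = c(
    "siku salama ni zipi baada ya hedhi",
    "nahesabu vipi siku salama za mzunguko",
    "hedhi yangu imechelewa nina wasiwasi"
  ),
  "female 20-24" = c(
    "nimekosa hedhi baada ya tendo bila kinga",
    "dawa ya dharura inafanya kazi baada ya siku ngapi",
    "sindano inaweza kuchelewesha hedhi yangu"
  ),
  "female 25-35" = c(
    "nataka kupata mtoto nianze lini",
    "njia gani inafaa mama wa watoto wawili",
    "naweza kutoa kipandikizi ili nipate mimba"
  ),
  "female 36+" = c(
    "dalili za saratani ya matiti ni zipi",
    "saratani ya mlango wa kizazi husababishwa na nini",
    "nipime wapi saratani ya kizazi"
  ),
  "male 15-19" = c(
    "je tendo bila kinga ni salama mara moja",
    "kondomu inaweza kupasuka wakati wa tendo",
    "natumia vipi kondomu kwa usahihi"
  ),
  "male 20-24" = c(
    "kondomu zinazuia ukimwi kabisa",
    "mpenzi wangu amekosa hedhi baada ya tendo",
    "nipate wapi kondomu za bure"
  ),
  "male 25-35" = c(
    "njia gani ya uzazi inafaa mke wangu",
    "tunawezaje kupanga nafasi ya watoto",
    "nini husababisha mbegu chache kwa wanaume"
  ),
  "male 36+" = c(
    "dalili za saratani ya tezi dume ni zipi",
    "tezi dume hupimwa vipi mapema",
    "nini husababisha kuvimba kwa tezi dume"
  )
)

.agent_pool_en <- c(
  "thank you for your question here is the information you requested",
  "the most common side effects are mild and pass within a few days",
  "you can visit your nearest clinic for free family planning services",
  "the emergency pill works best within three days of unprotected sex",
  "please let us know if you have any other questions about your health",
  "a nurse will follow up with more details about your question",
  "condoms used correctly protect against both pregnancy and infection",
  "your cycle can vary from month to month and that can be normal"
)

#' Default per-cohort topic lexicons
#'
#' Phrase pools by language (`en`, `sw`) and cohort (sex by age band) used
#' by [generate_corpus()]. Every cohort shares a core reproductive-health
#' vocabulary and adds cohort-specific topics; the term `"prostate"` occurs
#' only in the `male 36+` English pool, giving downstream rank analyses a
#' planted cohort-specific signal to recover.
#'
#' @return A list with elements `en` and `sw`, each a named list of phrase
#'   vectors keyed by cohort label, plus an `agents` pool for replies.
#' @export
default_topic_lexicons <- function() {
  cohorts <- names(.extras_en)
  en <- lapply(cohorts, function(ch) c(.core_en, rep(.extras_en[[ch]], 3)))
  sw <- lapply(cohorts, function(ch) c(.core_sw, rep(.extras_sw[[ch]], 3)))
  names(en) <- cohorts
  names(sw) <- cohorts
  list(en = en, sw = sw, agents = .agent_pool_en)
}
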