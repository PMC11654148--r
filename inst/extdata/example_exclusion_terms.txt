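# Example exclusion list for the PT-level signal table.
#
# Disproportionality screens of oncology drugs routinely surface terms that
# reflect the underlying disease or its management rather than the drug
# (disease progression, metastases, procedures). Curating them is a clinical
# judgment, so the pipeline only applies a user-editable list like this one;
# edit it to suit your own review. One preferred term per line; lines
# starting with '#' are ignored; case does not matter.
MALIGNANT NEOPLASM PROGRESSION
DISEASE PROGRESSION
METASTASES TO LIVER
METASTASES TO LUNG
NEOPLASM MALIGNANT
SURGERY
OFF LABEL USE
DRUG INEFFECTIVE
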