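# Tumour keywords. Matched case-insensitively at word boundaries; a match
# counts towards CRC only when linked to a colorectal site in the same
# sentence (see sites.txt) or when part of a compound term.
adenocarcinoma
adenocarcinomas
carcinoma
carcinomas
adenoca
cancer
cancers
tumour
tumours
tumor
tumors
malignancy
malignancies
malignant neoplasm
malignant lesion
malignant mass
malignant polyp
malignant stricture
malignant tumour
malignant tumor
neoplasm
neoplasms
neoplasia
mucinous adenocarcinoma
signet ring carcinoma
signet-ring carcinoma
signet ring cell carcinoma
adenosquamous carcinoma
medullary carcinoma
undifferentiated carcinoma
invasive carcinoma
invasive adenocarcinoma
residual carcinoma
residual adenocarcinoma
carcinomatosis
lesion
lesions
mass
tumour mass
neoplastic polyp
ca
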