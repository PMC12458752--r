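# Compound terms: self-sufficient CRC mentions that need no separate site
# link.
colorectal cancer
colorectal carcinoma
colorectal adenocarcinoma
colorectal tumour
colorectal tumor
colorectal malignancy
colon cancer
colon carcinoma
colonic adenocarcinoma
colonic carcinoma
rectal cancer
rectal carcinoma
rectal adenocarcinoma
rectal tumour
rectal tumor
sigmoid cancer
caecal cancer
bowel cancer
crc
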