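# Colorectal anatomical sites. A tumour keyword in the same sentence as a
# site term (within the linkage window) is considered colorectal.
caecum
caecal
cecum
cecal
ileocaecal valve
ileocecal valve
appendix
appendiceal
ascending colon
right colon
right hemicolon
hepatic flexure
transverse colon
splenic flexure
descending colon
left colon
left hemicolon
sigmoid
sigmoid colon
rectosigmoid
rectosigmoid junction
recto-sigmoid
rectum
rectal
mid rectum
low rectum
upper rectum
mesorectum
mesorectal
anorectal
anorectal junction
anal verge
colon
colonic
colorectal
large bowel
large intestine
bowel
bowel wall
caecal pole
pericolic
pericolonic
perirectal
presacral
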