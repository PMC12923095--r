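abdomen
abscess
anemia
aneurysm
angina
antibiotic
aorta
arrhythmia
arthritis
asthma
biopsy
cancer
carcinoma
cardiac
cardiovascular
cranial
coronary
dermatitis
diabetes
diagnosis
dialysis
digestive
discharge
dosage
dose
eczema
edema
embolism
fibrosis
fracture
gallbladder
gastric
glaucoma
heel
hepatitis
hernia
hypertension
icterus
infection
inflammation
insulin
ischemia
jaundice
kidney
knee
lesion
leukemia
liver
lymphoma
melanoma
metformin
migraine
mucosa
muscle
nausea
neoplasm
nephritis
neural
neurological
oral
pain
pancreas
pneumonia
prescription
prognosis
renal
sclera
scleral
seizure
sepsis
spine
stroke
symptom
syndrome
tendon
therapy
thrombosis
thyroid
tumor
ulcer
vein
vertigo
voxelotor
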