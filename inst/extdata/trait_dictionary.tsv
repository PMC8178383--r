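trait	category	description
CP	biotic	Claviceps purpurea resistance
FHB	biotic	Fusarium head blight resistance
LR	biotic	Leaf rust resistance
LS	biotic	Loose smut resistance
PM	biotic	Powdery mildew resistance
SBCMV	biotic	Soil-borne cereal mosaic virus resistance
SR	biotic	Stem rust resistance
STB	biotic	Septoria tritici blotch resistance
YR	biotic	Yellow rust resistance
CC	abiotic	Chlorophyll content
CIR	abiotic	Carbon isotope ratio
CL	abiotic	Coleoptile length
DB	abiotic	Dry biomass
FLRI	abiotic	Flag leaf rolling index
NDVI	abiotic	Normalized difference vegetation index
OP	abiotic	Osmotic potential
PDL	abiotic	Length of the ear peduncle
RRT	abiotic	Root related traits
SPAD	abiotic	Chlorophyll content (SPAD)
AX	quality	Arabinoxylan
BG	quality	Beta-glucan
Fb	quality	Flour yellow colour
GCaC	quality	Grain calcium concentration
GCuC	quality	Grain copper concentration
GFeC	quality	Grain iron concentration
GKC	quality	Grain potassium concentration
GMgC	quality	Grain magnesium concentration
GMnC	quality	Grain manganese concentration
GPC	quality	Grain protein content
GSC	quality	Grain sulphur concentration
GSeC	quality	Grain selenium concentration
GSeY	quality	Grain selenium yield
GZnC	quality	Grain zinc concentration
PGC	quality	Phosphorus grain concentration
SV	quality	SDS-sedimentation volume
YPC	quality	Yellow pigment content
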