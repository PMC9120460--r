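amber
amethyst
apricot
aqua
aquamarine
ash
azure
beige
black
blaze
blood
blue
blush
bean
boy
bronze
brown
burgundy
caramel
carmine
cerulean
charcoal
cherry
chestnut
chocolate
cinnamon
cobalt
colour
copper
coral
cream
crimson
cyan
dark
dune
ebony
electric
emerald
flame
fuchsia
ghost
gold
golden
green
grey
gray
hazel
honey
indigo
ivory
jade
jet
jungle
khaki
lavender
lemon
lilac
lime
magenta
mahogany
maroon
mauve
metallic
mint
mountain
mustard
navy
ochre
olive
onyx
opal
orange
orchid
pearl
peach
photo
pink
platinum
plum
purple
racing
rainbow
rainforest
red
rose
ruby
rust
saffron
salmon
sand
sapphire
scarlet
sea
sepia
sheen
silver
slate
smoke
snow
space
tan
taupe
teal
tree
turquoise
ultramarine
umber
vanilla
vermilion
violet
web
white
wine
yellow
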