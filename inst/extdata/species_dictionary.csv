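variant,canonical,scientific
london planetree,London Planetree,Platanus x acerifolia
london plane tree,London Planetree,Platanus x acerifolia
london plane,London Planetree,Platanus x acerifolia
planetree london,London Planetree,Platanus x acerifolia
honeylocust,Honeylocust,Gleditsia triacanthos
honey locust,Honeylocust,Gleditsia triacanthos
thornless honeylocust,Honeylocust,Gleditsia triacanthos
callery pear,Callery Pear,Pyrus calleryana
pear callery,Callery Pear,Pyrus calleryana
bradford pear,Callery Pear,Pyrus calleryana
norway maple,Norway Maple,Acer platanoides
maple norway,Norway Maple,Acer platanoides
pin oak,Pin Oak,Quercus palustris
oak pin,Pin Oak,Quercus palustris
littleleaf linden,Littleleaf Linden,Tilia cordata
little leaf linden,Littleleaf Linden,Tilia cordata
linden littleleaf,Littleleaf Linden,Tilia cordata
ginkgo,Ginkgo,Ginkgo biloba
gingko,Ginkgo,Ginkgo biloba
maidenhair tree,Ginkgo,Ginkgo biloba
green ash,Green Ash,Fraxinus pennsylvanica
ash green,Green Ash,Fraxinus pennsylvanica
red maple,Red Maple,Acer rubrum
maple red,Red Maple,Acer rubrum
silver maple,Silver Maple,Acer saccharinum
maple silver,Silver Maple,Acer saccharinum
japanese zelkova,Japanese Zelkova,Zelkova serrata
zelkova,Japanese Zelkova,Zelkova serrata
sweetgum,Sweetgum,Liquidambar styraciflua
sweet gum,Sweetgum,Liquidambar styraciflua
silver linden,Silver Linden,Tilia tomentosa
linden silver,Silver Linden,Tilia tomentosa
northern red oak,Northern Red Oak,Quercus rubra
red oak,Northern Red Oak,Quercus rubra
oak northern red,Northern Red Oak,Quercus rubra
american linden,American Linden,Tilia americana
basswood,American Linden,Tilia americana
linden american,American Linden,Tilia americana
other,Other,
hawthorn,Hawthorn,Crataegus
crabapple,Crabapple,Malus
crab apple,Crabapple,Malus
american elm,American Elm,Ulmus americana
elm american,American Elm,Ulmus americana
willow oak,Willow Oak,Quercus phellos
oak willow,Willow Oak,Quercus phellos
tree of heaven,Tree Of Heaven,Ailanthus altissima
ailanthus,Tree Of Heaven,Ailanthus altissima
eastern redbud,Eastern Redbud,Cercis canadensis
redbud,Eastern Redbud,Cercis canadensis
amur maple,Amur Maple,Acer ginnala
maple amur,Amur Maple,Acer ginnala
cherry,Cherry,Prunus
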