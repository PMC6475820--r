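# Demonstration recipe-to-ingredient map.
# Format: recipe_id<TAB>synonym...<TAB>|<TAB>ingredient...
# The recipe id (underscores read as spaces) is implicitly its own synonym.
gluten_free_pie_crust	gluten free crust	|	rice flour	potato starch flour	xanthan gum	shortening
gluten_free_pumpkin_bread	|	brown rice flour	xanthan gum	white sugar
gluten_free_banana_bread	|	rice flour	soy flour	white sugar	ground walnuts
gluten_free_peanut_butter_cookies	|	bean flour	white sugar	shortening
gluten_free_chocolate_chip_cookies	|	white rice flour	xanthan gum	shortening	white sugar
gluten_free_pancakes	|	brown rice flour	potato starch flour	xanthan gum
gluten_free_bread	|	brown rice flour	potato starch flour	xanthan gum
gluten_free_pizza_crust	|	white rice flour	potato starch flour	xanthan gum
gluten_free_brownies	|	bean flour	white sugar	shortening
gluten_free_muffins	|	rice flour	soy flour	white sugar
roasted_pumpkin_seeds	|	pumpkin seeds	olive oil
pumpkin_soup	|	pumpkin	cream
cinnamon_rolls	cinnamon buns	|	all purpose flour	white sugar	cinnamon
pumpkin_muffins	|	all purpose flour	pumpkin	white sugar
honey_cake	|	all purpose flour	honey	white sugar	dark rum
earthquake_cake	|	all purpose flour	white sugar	cream cheese
cucumber_salad	|	cucumber	vinegar
egg_salad	|	eggs	mayonnaise	pickles
pasta_salad	|	pasta	mayonnaise	pickles
broccoli_salad	|	broccoli	mayonnaise	sunflower seeds
fish_tacos	|	fish	all purpose flour	serrano chile
ratatouille	|	eggplant	zucchini	tomato
tomato_pie	|	tomato	all purpose flour	mayonnaise
tuna_noodle_casserole	|	pasta	tuna	all purpose flour
rum_punch	|	dark rum	peach schnapps	cherry
anisette_cookies	|	all purpose flour	anisette	white sugar
gin_fizz	gin cocktail	|	gin	cherry
jello_salad	|	gelatin	cherry	peach schnapps
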